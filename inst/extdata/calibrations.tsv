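tipA	tipB	ageMya
human	cattle	96
cattle	blue_whale	60
hippo	blue_whale	54
blue_whale	bottlenose_dolphin	33
blue_whale	minke_whale	10
sperm_whale	bottlenose_dolphin	30
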