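species	PLEC	EPPK1
human	1	1
cattle	1	1
blue_whale	1	0
bottlenose_dolphin	1	0
tasmanian_devil	1	1
platypus	1	1
kiwi	1	1
caecilian	1	1
zebrafish	2	1
skate	1	1
lamprey	0	0
sea_squirt	0	0
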