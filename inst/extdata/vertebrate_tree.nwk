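(sea_squirt:5.5,(lamprey:5.0,(skate:4.7,(zebrafish:4.3,(caecilian:3.5,(kiwi:3.2,(platypus:1.9,(tasmanian_devil:1.6,(human:0.96,(cattle:0.6,(blue_whale:0.33,bottlenose_dolphin:0.33)cetacea:0.23)cetartiodactyla:0.36)boreoeutheria:0.64)theria:0.3)mammalia:1.3)amniota:0.3)tetrapoda:0.8)osteichthyes:0.4)gnathostomata:0.3)vertebrata:0.5)chordata;
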