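ingredient,proportion_asfed
barley,0.1820
wheat,0.4992
rye,0.1000
sugar_beet_pulp,0.0250
soybean_meal,0.1530
vegetable_oil,0.0050
l_lysine,0.0050
dl_methionine,0.0010
l_threonine,0.0015
monocalcium_phosphate,0.0080
calcium_carbonate,0.0145
salt,0.0038
vitamin_mineral_premix,0.0020
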