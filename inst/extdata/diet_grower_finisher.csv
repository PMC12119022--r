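ingredient,proportion_asfed
barley,0.2700
wheat,0.4043
rye,0.1000
soybean_meal,0.1670
sunflower_meal,0.0200
vegetable_oil,0.0080
l_lysine,0.0045
dl_methionine,0.0007
l_threonine,0.0020
monocalcium_phosphate,0.0030
calcium_carbonate,0.0145
salt,0.0040
vitamin_mineral_premix,0.0020
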