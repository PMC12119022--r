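ingredient,proportion_asfed
barley,0.2000
wheat,0.5611
soybean_meal,0.1400
potato_protein,0.0250
fish_meal,0.0100
vegetable_oil,0.0180
l_lysine,0.0110
dl_methionine,0.0023
l_threonine,0.0030
l_tryptophan,0.0009
l_valine,0.0015
monocalcium_phosphate,0.0030
calcium_carbonate,0.0152
salt,0.0070
vitamin_mineral_premix,0.0020
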