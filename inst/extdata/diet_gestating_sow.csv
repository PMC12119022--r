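ingredient,proportion_asfed
barley,0.4720
wheat,0.2449
rye,0.1000
sugar_beet_pulp,0.0250
soy_hulls,0.0810
soybean_meal,0.0520
vegetable_oil,0.0050
monocalcium_phosphate,0.0020
calcium_carbonate,0.0125
salt,0.0020
vitamin_mineral_premix,0.0020
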