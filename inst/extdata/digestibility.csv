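ingredient,animal_class,d_om,d_cp,d_cf,d_starch_sugar
barley,growing,0.87,0.78,0.50,0.99
barley,sow,0.89,0.80,0.50,0.99
wheat,growing,0.90,0.86,0.50,0.99
wheat,sow,0.92,0.88,0.50,0.99
rye,growing,0.88,0.80,0.50,0.99
rye,sow,0.90,0.82,0.50,0.99
sugar_beet_pulp,growing,0.83,0.60,0.50,0.99
sugar_beet_pulp,sow,0.87,0.65,0.50,0.99
soy_hulls,growing,0.67,0.55,0.50,0.99
soy_hulls,sow,0.74,0.62,0.50,0.99
soybean_meal,growing,0.90,0.90,0.50,0.99
soybean_meal,sow,0.92,0.91,0.50,0.99
sunflower_meal,growing,0.72,0.82,0.50,0.99
sunflower_meal,sow,0.76,0.84,0.50,0.99
potato_protein,growing,0.94,0.95,0.50,0.99
potato_protein,sow,0.94,0.95,0.50,0.99
fish_meal,growing,0.92,0.92,0.90,0.99
fish_meal,sow,0.92,0.92,0.90,0.99
vegetable_oil,growing,0.92,0.80,0.92,0.99
vegetable_oil,sow,0.92,0.80,0.92,0.99
wheat_bran,growing,0.64,0.72,0.50,0.99
wheat_bran,sow,0.68,0.74,0.50,0.99
oats,growing,0.74,0.80,0.50,0.99
oats,sow,0.77,0.82,0.50,0.99
l_lysine,growing,1.0,1.0,1.0,0.99
l_lysine,sow,1.0,1.0,1.0,0.99
dl_methionine,growing,1.0,1.0,1.0,0.99
dl_methionine,sow,1.0,1.0,1.0,0.99
l_threonine,growing,1.0,1.0,1.0,0.99
l_threonine,sow,1.0,1.0,1.0,0.99
l_tryptophan,growing,1.0,1.0,1.0,0.99
l_tryptophan,sow,1.0,1.0,1.0,0.99
l_valine,growing,1.0,1.0,1.0,0.99
l_valine,sow,1.0,1.0,1.0,0.99
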