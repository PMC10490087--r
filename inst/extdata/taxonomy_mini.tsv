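fine	middle	coarse
meatball	red meat	meat
beef steak	red meat	meat
chicken breast	poultry	meat
chicken curry	poultry	meat
white rice	grains	cereals and potatoes
spaghetti	grains	cereals and potatoes
bread white	grains	cereals and potatoes
mashed potato	potatoes	cereals and potatoes
french fries	potatoes	cereals and potatoes
water	cold drinks	liquids
orange juice	cold drinks	liquids
cola	cold drinks	liquids
coffee black	hot drinks	liquids
milk coffee	hot drinks	liquids
chocolate cake	sweets	dessert
ice cream	sweets	dessert
apple	fruits and vegetables	fruits vegetables nuts
banana	fruits and vegetables	fruits vegetables nuts
carrot salad	fruits and vegetables	fruits vegetables nuts
olive oil	fruits and vegetables	fruits vegetables nuts
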