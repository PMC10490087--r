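fine_category,density_g_per_mL,kcal_per_100g,cho_g_per_100g,protein_g_per_100g,fat_g_per_100g,serving_volume_mL
meatball,0.97,230,6,15,16,150
beef steak,1.05,250,0,26,16,180
chicken breast,1.05,165,0,31,3.6,150
chicken curry,1.00,150,6,12,9,250
white rice,0.86,130,28,2.7,0.3,160
spaghetti,0.80,158,31,5.8,0.9,200
bread white,0.27,265,49,9,3.2,90
mashed potato,0.95,88,15,2,2.5,210
french fries,0.58,312,41,3.4,15,170
water,1.00,0,0,0,0,250
orange juice,1.04,45,10.4,0.7,0.2,250
cola,1.04,42,10.6,0,0,330
coffee black,1.00,2,0.4,0.1,0,200
milk coffee,1.02,35,4,1.7,1.5,220
chocolate cake,0.45,370,50,5,17,120
ice cream,0.55,207,24,3.5,11,130
apple,0.60,52,12.5,0.3,0.2,180
banana,0.94,89,23,1.1,0.3,120
carrot salad,0.55,45,8,1,1.2,150
olive oil,0.91,800,0,0,90,15
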