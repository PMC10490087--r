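fine_category,density_g_per_mL,kcal_per_100g,cho_g_per_100g,protein_g_per_100g,fat_g_per_100g,serving_volume_mL
apple pie,0.60,237,34,2,11,125
lentil soup,1.00,55,8,3.5,1,300
white rice,0.88,135,29,2.8,0.4,150
porridge,1.05,71,12,2.5,1.5,240
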