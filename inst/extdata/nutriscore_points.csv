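category,component,gt,points
general,energy_kj,335,1
general,energy_kj,670,2
general,energy_kj,1005,3
general,energy_kj,1340,4
general,energy_kj,1675,5
general,energy_kj,2010,6
general,energy_kj,2345,7
general,energy_kj,2680,8
general,energy_kj,3015,9
general,energy_kj,3350,10
general,sugars_g,4.5,1
general,sugars_g,9,2
general,sugars_g,13.5,3
general,sugars_g,18,4
general,sugars_g,22.5,5
general,sugars_g,27,6
general,sugars_g,31,7
general,sugars_g,36,8
general,sugars_g,40,9
general,sugars_g,45,10
general,satfat_g,1,1
general,satfat_g,2,2
general,satfat_g,3,3
general,satfat_g,4,4
general,satfat_g,5,5
general,satfat_g,6,6
general,satfat_g,7,7
general,satfat_g,8,8
general,satfat_g,9,9
general,satfat_g,10,10
general,sodium_mg,90,1
general,sodium_mg,180,2
general,sodium_mg,270,3
general,sodium_mg,360,4
general,sodium_mg,450,5
general,sodium_mg,540,6
general,sodium_mg,630,7
general,sodium_mg,720,8
general,sodium_mg,810,9
general,sodium_mg,900,10
general,fruitveg_pct,40,1
general,fruitveg_pct,60,2
general,fruitveg_pct,80,5
general,fibre_g,0.9,1
general,fibre_g,1.9,2
general,fibre_g,2.8,3
general,fibre_g,3.7,4
general,fibre_g,4.7,5
general,protein_g,1.6,1
general,protein_g,3.2,2
general,protein_g,4.8,3
general,protein_g,6.4,4
general,protein_g,8,5
beverage,energy_kj,0,1
beverage,energy_kj,30,2
beverage,energy_kj,60,3
beverage,energy_kj,90,4
beverage,energy_kj,120,5
beverage,energy_kj,150,6
beverage,energy_kj,180,7
beverage,energy_kj,210,8
beverage,energy_kj,240,9
beverage,energy_kj,270,10
beverage,sugars_g,0,1
beverage,sugars_g,1.5,2
beverage,sugars_g,3,3
beverage,sugars_g,4.5,4
beverage,sugars_g,6,5
beverage,sugars_g,7.5,6
beverage,sugars_g,9,7
beverage,sugars_g,10.5,8
beverage,sugars_g,12,9
beverage,sugars_g,13.5,10
beverage,satfat_g,1,1
beverage,satfat_g,2,2
beverage,satfat_g,3,3
beverage,satfat_g,4,4
beverage,satfat_g,5,5
beverage,satfat_g,6,6
beverage,satfat_g,7,7
beverage,satfat_g,8,8
beverage,satfat_g,9,9
beverage,satfat_g,10,10
beverage,sodium_mg,90,1
beverage,sodium_mg,180,2
beverage,sodium_mg,270,3
beverage,sodium_mg,360,4
beverage,sodium_mg,450,5
beverage,sodium_mg,540,6
beverage,sodium_mg,630,7
beverage,sodium_mg,720,8
beverage,sodium_mg,810,9
beverage,sodium_mg,900,10
beverage,fruitveg_pct,40,2
beverage,fruitveg_pct,60,4
beverage,fruitveg_pct,80,10
beverage,fibre_g,0.9,1
beverage,fibre_g,1.9,2
beverage,fibre_g,2.8,3
beverage,fibre_g,3.7,4
beverage,fibre_g,4.7,5
beverage,protein_g,1.6,1
beverage,protein_g,3.2,2
beverage,protein_g,4.8,3
beverage,protein_g,6.4,4
beverage,protein_g,8,5
added_fat,satfat_ratio_pct,10,1
added_fat,satfat_ratio_pct,16,2
added_fat,satfat_ratio_pct,22,3
added_fat,satfat_ratio_pct,28,4
added_fat,satfat_ratio_pct,34,5
added_fat,satfat_ratio_pct,40,6
added_fat,satfat_ratio_pct,46,7
added_fat,satfat_ratio_pct,52,8
added_fat,satfat_ratio_pct,58,9
added_fat,satfat_ratio_pct,64,10
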