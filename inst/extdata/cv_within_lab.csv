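name,stc_ug_kg,cv_r_pct
Amoxicillin,4,9.7
Ampicillin,4,7.1
Cloxacillin,15,3.6
Dicloxacillin,15,6.6
Nafcillin,15,7.0
Oxacillin,15,4.9
Penicillin G,4,14.2
Penicillin V,4,16.2
Cefalexin,25,7.1
Cefazolin,25,4.5
Cefapirin,25,6.3
Cefquinome,10,11.2
Cefoperazone,25,4.3
Ceftiofur,50,5.1
Chlortetracycline,50,4.9
Doxycycline,50,8.3
Oxytetracycline,50,7.8
Tetracycline,50,5.3
Epi-Chlortetracycline,50,3.3
Epi-Doxycycline,50,2.7
Epi-Oxytetracycline,50,5.6
Epi-Tetracycline,50,3.7
Tiamulin,10,6.7
Valnemulin,10,11.5
Tilmicosin,20,7.0
Tylosin,20,8.6
Azithromycin,20,2.9
Erythromycin,20,4.4
Spiramycin,20,4.3
Clindamycin,75,4.8
Lincomycin,75,4.2
Nalidixic Acid,15,10.9
Oxolinic Acid,15,5.1
Ciprofloxacin,15,4.7
Danofloxacin,15,4.1
Difloxacin,15,6.0
Enrofloxacin,15,4.5
Flumequine,15,6.4
Marbofloxacin,15,5.1
Norfloxacin,15,6.5
Ofloxacin,15,5.9
Sarafloxacin,15,3.4
Sulfaquinoxaline,50,6.2
Sulfachloropyridazine,50,4.9
Sulfadiazine,50,6.4
Sulfadimethoxine,50,7.7
Sulfaguanidine,50,18.5
Sulfamerazine,50,6.4
Sulfamethazine,50,6.0
Sulfamethizole,50,5.7
Sulfamethoxazole,50,5.0
Sulfamethoxypyridazine,50,3.2
Sulfamonomethoxine,50,3.5
Sulfanilamide,50,6.2
Sulfapyridine,50,3.5
Sulfathiazole,50,3.9
Trimethoprim,50,7.1
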