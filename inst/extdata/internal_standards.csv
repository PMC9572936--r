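name,formula,adduct,rt_min,conc_ug_kg
Sulfanilamide-13C6,[13C]6H8N2O2S,[M+H-NH3]+,3.65,10
Cefadroxil-d4,C16H13[2H]4N3O5S,[M+H]+,9.50,10
Enrofloxacin-d5,C19H17[2H]5FN3O3,[M+H]+,10.66,10
Penicillin G-d7,C16H11[2H]7N2O4S,[M+Na]+,15.90,10
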