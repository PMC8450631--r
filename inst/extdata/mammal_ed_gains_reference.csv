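# Published reference values: the ten extant mammal species with the
# largest gains in equal-splits evolutionary distinctiveness (Myr) caused
# by mammal extinctions over the past ~130,000 years, computed from a
# global mammal phylogeny including recently extinct taxa. Shipped for
# narrative comparison only; reproducing these exactly requires the
# external mammal phylogeny and extinction list, and depends on which
# posterior tree is used.
species,common_name,ed_extant,ed_pre_extinction,ed_gain
Elephas maximus,Asian elephant,47.69,10.00,37.69
Solenodon cubanus,Cuban solenodon,66.45,32.60,33.85
Dugong dugon,dugong,60.50,30.86,29.64
Loxodonta africana,African bush elephant,47.69,19.86,27.83
Macrotis lagotis,greater bilby,45.85,19.73,26.12
Tachyglossus aculeatus,short-beaked echidna,74.61,49.04,25.57
Hippopotamus amphibius,common hippopotamus,33.28,9.14,24.14
Zaglossus bruijnii,western long-beaked echidna,39.05,16.62,22.43
Tapirus indicus,Malayan tapir,40.52,20.37,20.15
Choloepus didactylus,Linnaeus's two-toed sloth,25.59,7.31,18.27
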