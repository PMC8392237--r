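"code","name","resistance","habitat_suitability","habitat_score","ndvi_base","is_water","is_cropland"
1,"paddy_field",100,0.4,5,0.55,FALSE,TRUE
2,"irrigated_land",90,0.35,5,0.5,FALSE,TRUE
3,"forestland",1,1,7,0.8,FALSE,FALSE
4,"grassland",50,0.7,5,0.6,FALSE,FALSE
5,"river",10,0.9,7,0.1,TRUE,FALSE
6,"lake",10,0.9,7,0.1,TRUE,FALSE
7,"urban",800,0,1,0.15,FALSE,FALSE
8,"rural",700,0.05,1,0.2,FALSE,FALSE
9,"mine",1000,0,1,0.1,FALSE,FALSE
10,"bare",50,0.1,3,0.25,FALSE,FALSE
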