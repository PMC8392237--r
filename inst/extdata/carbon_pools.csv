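"code","name","c_above","c_below","c_soil","c_dead"
1,"paddy_field",8,2,65,1
2,"irrigated_land",7,2,60,1
3,"forestland",60,15,90,5
4,"grassland",10,4,70,1
5,"river",0,0,0,0
6,"lake",0,0,0,0
7,"urban",2,1,20,0
8,"rural",3,1,25,0
9,"mine",0,0,5,0
10,"bare",1,0,10,0
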