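barrier_name,stage,focal,method,value,available
ecogeography,prepollination,white_sand,RI4C,0.83,TRUE
phenology,prepollination,white_sand,RI4S2,-0.23,TRUE
pollinators,prepollination,white_sand,RI4C,0.82,TRUE
pollen_adhesion,postpollination_prezygotic,white_sand,RI4A,NA,FALSE
pollen_germination,postpollination_prezygotic,white_sand,RI4A,NA,FALSE
seed_development,postzygotic,white_sand,RI4A,NA,FALSE
ecogeography,prepollination,brown_sand,RI4C,0.45,TRUE
phenology,prepollination,brown_sand,RI4S2,0.69,TRUE
pollinators,prepollination,brown_sand,RI4C,0.82,TRUE
pollen_adhesion,postpollination_prezygotic,brown_sand,RI4A,0.18,TRUE
pollen_germination,postpollination_prezygotic,brown_sand,RI4A,0.02,TRUE
seed_development,postzygotic,brown_sand,RI4A,0.40,TRUE
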