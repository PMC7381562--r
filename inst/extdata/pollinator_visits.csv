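morphospecies,white_sand,brown_sand
bee_morph_A,22,4
bee_morph_B,6,4
bee_morph_C,9,84
bee_morph_D,0,2
bee_morph_E,0,9
bee_morph_F,0,10
bee_morph_G,0,7
bee_morph_H,0,1
bee_morph_I,2,34
bee_morph_J,0,10
bee_morph_K,0,2
green_fly,0,8
brown_wasp,0,1
black_wasp,0,1
lepidoptera,1,0
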