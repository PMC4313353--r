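((((((human:25,(macaque:15,vervet:15):10):17,marmoset:42):43,treeshrew:85):5,(((mouse:20,rat:20):50,(guinea_pig:35,naked_mole_rat:35):35):10,rabbit:80):10):15,(((((cow:25,sheep:25):30,(dolphin:35,sei_whale:35):20):7,pig:62):13,((dog:45,ferret:45):10,cat:55):20):5,horse:80):25):75,opossum:180);
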