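(Thismia_thaithongiana:1,((Thismia_hawkesii:1,(Thismia_mucronata:1,Thismia_puberula:1):1):1,((Thismia_hongkongensis:1,Thismia_tentaculata:1):1,(Thismia_gardneriana:1,(Thismia_lanternata:1,((Thismia_neptunis:1,Thismia_kelabitiana:1):1,(Thismia_filiformis:1,(Thismia_alba:1,Thismia_hexagona:1):1):1):1):1):1):1):1);
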