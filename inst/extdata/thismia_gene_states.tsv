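taxon	accD	rpl2	rrn16	rrn23	trnE	rps2	rps18	rps3	rps4	rps8
Thismia_thaithongiana	intact	intact	intact	intact	intact	absent	intact	pseudogene	pseudogene	pseudogene
Thismia_hawkesii	intact	intact	intact	intact	intact	absent	intact	intact	intact	intact
Thismia_mucronata	intact	intact	intact	intact	intact	intact	intact	intact	intact	intact
Thismia_puberula	intact	intact	intact	intact	intact	intact	intact	intact	intact	intact
Thismia_hongkongensis	intact	intact	intact	intact	intact	pseudogene	intact	intact	intact	intact
Thismia_tentaculata	intact	intact	intact	intact	intact	intact	intact	pseudogene	intact	intact
Thismia_gardneriana	intact	intact	intact	intact	intact	intact	intact	pseudogene	intact	pseudogene
Thismia_lanternata	intact	intact	intact	intact	intact	intact	intact	intact	pseudogene	intact
Thismia_neptunis	intact	intact	intact	intact	intact	intact	pseudogene	intact	intact	intact
Thismia_kelabitiana	intact	intact	intact	intact	intact	intact	intact	intact	intact	unsampled
Thismia_filiformis	intact	intact	intact	intact	intact	intact	absent	intact	pseudogene	intact
Thismia_alba	intact	intact	intact	intact	intact	intact	absent	intact	intact	intact
Thismia_hexagona	intact	intact	intact	intact	intact	intact	absent	intact	intact	intact
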