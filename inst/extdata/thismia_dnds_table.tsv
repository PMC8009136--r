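gene	label	omega_thismia	omega_photo	p_value	q_printed
accD	accD	0.41	0.29	NA	0.01
rpl2	rpl2	0.32	0.23	0.59	0.59
rps2	rps2	0.43	0.13	8.26e-8	4.54e-7
rps3	rps3	0.35	0.12	1.09e-6	2.40e-6
rps3	rps3_atypical_start_excluded	0.47	0.12	4.45e-7	1.22e-6
rps4	rps4	0.36	0.1	2.86e-7	1.05e-6
rps4	rps4_atypical_start_excluded	0.37	0.1	6.80e-8	7.48e-7
rps8	rps8	0.23	0.26	0.49	0.54
rps8	rps8_atypical_start_excluded	0.26	0.26	0.24	0.30
rps12	rps12	0.25	0.03	NA	0.00
rps18	rps18	0.44	0.31	NA	0.00
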