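mirna_id	stemloops	mean_knockdown	mean_control	log2fc	probability
miR-124-3p	mir-124-1,mir-124-2,mir-124-3	314.8	28.0	3.49	0.97
miR-410-3p	mir-410	149.8	7.9	4.24	0.96
miR-1307-3p	mir-1307	73.4	569.2	-2.95	0.96
miR-33a-5p	mir-33a	42.3	4.7	3.18	0.93
miR-1307-5p	mir-1307	18.5	2.1	3.16	0.90
miR-27b-3p	mir-27b	589.0	142.1	2.05	0.90
miR-1268a	mir-1268a	80.2	16.0	2.32	0.89
miR-27a-3p	mir-27a	68.2	14.5	2.23	0.88
mir-873	mir-873	66.4	14.1	2.23	0.88
miR-92a-1-5p	mir-92a-1	108.4	377.0	-1.80	0.87
miR-331-3p	mir-331	32.4	7.1	2.19	0.85
miR-1268b	mir-1268b	89.8	25.6	1.81	0.85
miR-130a-3p	mir-130a	78.4	21.5	1.87	0.85
miR-377-3p	mir-377	18.8	4.1	2.19	0.84
miR-221-5p	mir-221	3.7	16.9	-2.19	0.83
miR-423-5p	mir-423	2111.4	5697.1	-1.43	0.81
miR-181d-5p	mir-181d	167.7	505.2	-1.59	0.81
miR-345-5p	mir-345	10.6	2.7	1.96	0.81
miR-887-3p	mir-887	3.6	12.2	-1.77	0.80
miR-92b-5p	mir-92b	30.7	90.9	-1.56	0.79
miR-487b-3p	mir-487b	249.7	96.9	1.37	0.78
miR-181b-5p	mir-181b-1,mir-181b-2	862.6	2181.6	-1.34	0.75
miR-296-5p	mir-296	11.5	3.8	1.59	0.72
miR-496	mir-496	10.3	3.5	1.54	0.72
miR-320a	mir-320a	11660.9	24018.5	-1.04	0.70
miR-323a-3p	mir-323a	1147.6	537.4	1.09	0.70
miR-7-5p	mir-7-1,mir-7-2,mir-7-3	38.4	91.5	-1.25	0.70
miR-505-5p	mir-505	16.3	39.2	-1.27	0.67
miR-93-5p	mir-93	714.4	361.2	0.98	0.67
miR-221-3p	mir-221	131.1	257.8	-0.98	0.66
miR-181a-5p	mir-181a-1,mir-181a-2	3045.0	5580.8	-0.87	0.65
miR-2110	mir-2110	4.0	10.1	-1.34	0.65
miR-760	mir-760	12.8	28.5	-1.15	0.64
miR-377-5p	mir-377	59.8	29.6	1.02	0.64
miR-363-3p	mir-363	13.2	5.4	1.29	0.64
miR-412-5p	mir-412	4.8	11.2	-1.23	0.63
miR-24-3p	mir-24-1,mir-24-2	959.0	547.1	0.81	0.63
miR-330-3p	mir-330	58.2	106.3	-0.87	0.62
miR-1301-3p	mir-1301	106.8	185.2	-0.79	0.62
miR-382-5p	mir-382	266.3	157.3	0.76	0.61
miR-222-3p	mir-222	578.5	959.9	-0.73	0.61
miR-323b-3p	mir-323b	10.1	4.7	1.09	0.61
miR-25-3p	mir-25	1434.6	875.3	0.71	0.61
miR-376c-3p	mir-376c	70.1	39.8	0.82	0.60
miR-361-5p	mir-361	16.6	8.4	0.99	0.60
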