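mirna_id	stemloops	regulation	n_targets	three_node	three_node_sig	four_node	four_node_sig
miR-124-3p	mir-124-1,mir-124-3	R	2079	138	TRUE	296	FALSE
miR-33a-5p	mir-33a	R	1212	51	FALSE	214	TRUE
miR-1307-5p	mir-1307	R	0	0	FALSE	0	FALSE
miR-1268a	mir-1268a	R	31	1	FALSE	1	FALSE
miR-27a-3p	mir-27a	R	2264	115	FALSE	303	FALSE
miR-27b-3p	mir-27b	R	2307	115	FALSE	308	FALSE
miR-345-5p	mir-345	R	72	10	TRUE	7	FALSE
miR-1268b	mir-1268b	R	8	0	FALSE	0	FALSE
miR-296-5p	mir-296	R	169	16	TRUE	31	FALSE
miR-93-5p	mir-93	R	1916	130	TRUE	352	TRUE
miR-24-3p	mir-24-1,mir-24-2	R	1557	94	TRUE	365	TRUE
miR-25-3p	mir-25	R	1247	62	FALSE	188	FALSE
miR-181a-5p	mir-181a-1,mir-181a-2	A	1321	76	TRUE	307	TRUE
miR-330-3p	mir-330	A	689	45	TRUE	94	FALSE
miR-320a	mir-320a	A	1204	74	TRUE	292	TRUE
miR-760	mir-760	A	250	14	FALSE	22	FALSE
miR-7-5p	mir-7-1,mir-7-2	A	1909	89	FALSE	274	FALSE
miR-181b-5p	hsa-mir-181b-1,hsa-mir-181b-2	A	1348	79	TRUE	316	TRUE
miR-2110	mir-2110	A	213	17	TRUE	30	FALSE
miR-92b-5p	mir-92b	A	4	0	FALSE	1	FALSE
miR-181d-5p	mir-181d	A	1257	73	TRUE	286	TRUE
miR-887-3p	mir-887	A	8	0	FALSE	2	FALSE
miR-92a-1-5p	mir-92a-1	A	49	2	FALSE	16	FALSE
miR-1307-3p	mir-1307	A	2	0	FALSE	0	FALSE
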