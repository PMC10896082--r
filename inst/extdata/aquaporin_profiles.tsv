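gene_id	blast_name	meam1_gene	h2_res	h2_pos	h5_res	h5_pos	le1_res	le1_pos	le2_res	le2_pos	npa_b	npa_e	log_cpm	fold
ENSSSA1UGG010352	Aquaporin 1	Bta01973	F	71	H	89	A	207	R	213	91	210	8.49	32.7
ENSSSA1UGG000288	Aquaporin 2A	Bta13786	F	183	H	201	A	319	R	325	204	322	NA	NA
ENSSSA1UGG011828	Aquaporin 5	Bta07507	F	63	I	80	S	199	R	205	82	202	NA	NA
ENSSSA1UGG011821	Aquaporin 6	Bta07504	F	139	H	157	A	280	R	286	159	283	5.17	2.2
ENSSSA1UGG005288	Aquaporin AQPAe.a	Bta03161	F	61	H	80	T	195	R	201	82	198	NA	NA
ENSSSA1UGG001892	Aquaporin 7 (AQP 12L)	Bta14320	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	3.31	2.1
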