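gene_id	meam1_gene	log_cpm	fold	signal_peptide	d_score	cleavage_site	nucleophile_res	nucleophile_pos	proton_donor_res	proton_donor_pos
ENSSSA1UGG005530	Bta06059	1.05	52.71	+	0.760	A(19)F	D	224	E	289
ENSSSA1UGG000414	Bta07377	8.14	30.06	+	0.768	S(20)R	D	227	E	295
ENSSSA1UGG008427	Bta14419	10.44	29.65	+	0.474	S(20)H	D	230	E	297
ENSSSA1UGG005077	Bta05340	2.04	28.25	+	0.739	G(21)H	D	183	E	250
ENSSSA1UGG009590	Bta09633	4.35	28.25	+	0.774	C(20)N	D	227	E	295
ENSSSA1UGG013152	Bta04298	10.09	27.67	-	0.195	NA	D	19	E	86
ENSSSA1UGG000718	Bta03818	9.43	25.99	+	0.843	C(16)R	D	228	E	296
ENSSSA1UGG004292	Bta07764	7.35	25.46	+	0.512	E(20)E	D	257	E	289
ENSSSA1UGG002701	Bta12682	11.23	25.11	-	0.119	NA	D	288	E	344
ENSSSA1UGG002293	Bta03439	10.18	24.93	+	0.833	A(22)Q	D	227	E	232
ENSSSA1UGG012024	Bta08425	9.96	23.92	+	0.825	G(20)I	D	231	E	290
ENSSSA1UGG009983	Bta05396	9.93	23.43	-	0.329	NA	D	244	E	312
ENSSSA1UGG005217	Bta08427	7.12	22.63	+	0.860	G(20)V	D	227	E	286
ENSSSA1UGG009974	Bta05386	11.05	21.71	+	0.743	A(24)V	D	268	E	337
ENSSSA1UGG007699	Bta06458	9.12	20.25	+	0.765	G(20)G	E	229	R	287
ENSSSA1UGG001314	Bta09696	5.07	20.25	+	0.742	A(25)Q	NA	NA	NA	NA
ENSSSA1UGG005058	Bta14422	9.04	17.27	+	0.799	Q(23)S	D	228	E	296
ENSSSA1UGG013610	Bta10022	4.74	17.27	-	0.147	NA	NA	NA	NA	NA
ENSSSA1UGG000756	Bta07452	8.99	11.00	-	0.428	NA	D	227	E	294
ENSSSA1UGG003676	Bta11358	2.71	8.51	+	0.810	A(20)D	NA	NA	NA	NA
ENSSSA1UGG005127	Bta15649	11.25	17.15	+	0.693	E(21)F	D	233	E	300
ENSSSA1UGG000967	Bta01478	7.17	7.36	-	0.105	NA	D	281	E	369
ENSSSA1UGG003278	Bta13914	3.35	4.41	+	0.805	S(17)T	D	220	E	288
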