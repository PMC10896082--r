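gene_id	description	gene_symbol	pathway	log_cpm	fold	origin_genus	meam1_gene
ENSSSA1UGG005107	2OG-Fe (II) oxygenase	NA	Arg, Proline	11.16	1.00	Pantoea	Bta20012
ENSSSA1UGG004185	4-hydroxy-tetrahydrodipicolinate reductase	dapB	L-lysine	7.88	5.45	Rickettsia	Bta20020
ENSSSA1UGG003633	Diaminopimelate decarboxylase	lysA	L-lysine	6.89	13.89	Planctomyces	Bta03593
ENSSSA1UGG006878	Diaminopimelate epimerase	dapF	L-lysine	0.13	1.57	Klebsiella	Bta06657
ENSSSA1UGG006186	ATP-dependent dethiobiotin synthetase	bioD	Biotin	6.69	7.11	Wolbachia	Bta01938
ENSSSA1UGG001672	Arginosuccinate lyase	argH	L-arginine	6.68	1.79	Erwinia	Bta00063
ENSSSA1UGG001722	Arginosuccinate synthase	argG	L-arginine	5.95	2.10	Pantoea/Erwinia	Bta00062
ENSSSA1UGT031701	Biotin synthase	bioB	Biotin	5.21	1.41	Not well defined	Bta09725
ENSSSA1UGG006186	ATP-dependent dethiobiotin synthetase	bioD	Biotin	5.16	-1.50	Wolbachia	Bta00840
ENSSSA1UGG012028	Chorismate mutase	CM	shikimate	5.01	2.57	Rahnella	Bta15103
ENSSSA1UGG001160	3-methyl-2-oxobutanoate hydroxymethyltransferase	panB	Pantothenate	3.57	30.50	Pseudomonas	Bta05339
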