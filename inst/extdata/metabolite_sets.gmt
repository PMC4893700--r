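glutathione_gamma_glutamyl	metabotox default metabolite set	GSH	GSSG	CSSG	Ophthalmic acid	gamma-Glutamylglutamate	gamma-Glutamylglutamine	gamma-Glutamylcysteine	Glutamate	Glutamine	5-Oxoproline	Cysteinylglycine	Cysteine
amino_acids	metabotox default metabolite set	Glycine	Alanine	Serine	Proline	Valine	Threonine	Leucine	Isoleucine	Asparagine	Aspartate	Lysine	Methionine	Histidine	Phenylalanine	Arginine	Tyrosine	Tryptophan	Ornithine	Citrulline	Taurine
acylcarnitines	metabotox default metabolite set	Carnitine	Acetylcarnitine	Propionylcarnitine	Butyrylcarnitine	Hexanoylcarnitine	Octanoylcarnitine	Decanoylcarnitine	Lauroylcarnitine	Myristoylcarnitine	Palmitoylcarnitine
fatty_acids	metabotox default metabolite set	FA 12:0	FA 14:0	FA 16:0	FA 16:1	FA 17:0	FA 18:0	FA 18:1	FA 18:2	FA 18:3	FA 20:0	FA 20:3	FA 20:4	FA 20:5	FA 22:0	FA 22:6	FA 24:0
triacylglycerols	metabotox default metabolite set	TG 48:0	TG 48:1	TG 48:2	TG 50:1	TG 50:2	TG 50:3	TG 52:1	TG 52:2	TG 52:3	TG 52:4	TG 54:2	TG 54:3	TG 54:4	TG 54:5	TG 54:6	TG 56:4	TG 56:6	TG 56:8
diacylglycerols	metabotox default metabolite set	DG 32:0	DG 34:1	DG 34:2	DG 36:2	DG 36:3	DG 36:4	DG 38:4	DG 38:6
phospholipids	metabotox default metabolite set	PC 30:0	PC 32:0	PC 32:1	PC 34:1	PC 34:2	PC 36:1	PC 36:2	PC 36:3	PC 36:4	PC 38:4	PC 38:5	PC 38:6	PC 40:6	PC 40:7	PE 34:1	PE 34:2	PE 36:1	PE 36:2	PE 36:4	PE 38:4	PE 38:6	PE 40:6
lysophospholipids	metabotox default metabolite set	LPC 14:0	LPC 16:0	LPC 16:1	LPC 18:0	LPC 18:1	LPC 18:2	LPC 20:3	LPC 20:4	LPC 22:6	LPE 16:0	LPE 18:0	LPE 18:1	LPE 18:2	LPE 20:4
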