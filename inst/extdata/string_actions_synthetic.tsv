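item_id_a	item_id_b	mode	action	is_directional	a_is_acting	score	taxon
GENE_A	GENE_B	activation	activation	t	t	900	9606
GENE_B	GENE_A	activation	activation	t	f	900	9606
GENE_A	GENE_C	inhibition	inhibition	t	t	850	9606
GENE_A	GENE_C	activation	activation	t	t	820	9606
GENE_C	GENE_D	binding		f	f	950	9606
GENE_D	GENE_E	activation	activation	t	t	799	9606
GENE_E	GENE_F	inhibition	inhibition	t	t	950	10090
GENE_F	GENE_F	activation	activation	t	t	880	9606
GENE_G	GENE_H	activation	activation	t	t	NA	9606
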