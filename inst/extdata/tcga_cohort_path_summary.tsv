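dataset	meth_class	n_close	n_with_path	close_proportion	avg_distance
CHOL	large	126	1119	0.11	2.07
COAD	large	51	796	0.06	2.05
LIHC	large	21	571	0.04	1.76
LUSC	large	108	923	0.12	2.00
KIRP	large	24	371	0.06	1.88
THCA	large	12	148	0.08	2.58
CHOL	normal	215	3802	0.05	2.15
COAD	normal	51	2978	0.02	2.10
LIHC	normal	58	2854	0.02	2.00
LUSC	normal	179	4559	0.04	2.06
KIRP	normal	65	2754	0.02	2.12
THCA	normal	27	854	0.03	2.21
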