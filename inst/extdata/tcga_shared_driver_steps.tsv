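driver	THCA	CHOL	COAD	KIRP	LUSC	LIHC
AGTR1	3	2	2	-	2	1
IGF1	-	0	1	1	1	1
CXCL12	-	1	1	-	1	2
FGFR3	2	0	-	-	0	-
EPAS1	-	0	0	-	0	-
SRC	-	0	-	0	-	1
FOXD3	-	-	0	0	-	0
PPARG	1	1	-	-	-	-
FOXO1	-	1	-	0	-	-
CDK4	-	1	-	-	2	-
NKX3-1	-	1	-	-	-	1
PIK3R1	-	0	-	-	0	-
PRKCB	-	-	1	-	1	-
EDNRB	-	-	0	-	0	-
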