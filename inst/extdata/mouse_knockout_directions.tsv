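# Mouse knockout effects on lean mass and grip strength for sarcopenia-panel
# genes with a significant (p < 0.05) knockout phenotype: 12 knockouts decrease
# lean mass/strength (direction -1), 15 increase them (direction +1).
# expression_direction: sign of the human protective allele's association with
# the gene's expression, where reported (+1 increased, -1 decreased); NA otherwise.
gene	knockout_direction	knockout_significant	expression_direction	eqtl_rsid	eqtl_allele
ADCY3	-1	TRUE	1	rs10203386	T
AOC1	-1	TRUE	NA	NA	NA
BCKDHB	-1	TRUE	1	rs9350850	C
BTNL2	-1	TRUE	NA	NA	NA
CDKAL1	-1	TRUE	NA	NA	NA
CEP192	-1	TRUE	1	rs1786263	G
GDF5	-1	TRUE	NA	NA	NA
H1FX	-1	TRUE	1	rs4073154	G
POLD3	-1	TRUE	1	rs72977282	T
RBL2	-1	TRUE	NA	NA	NA
SWT1	-1	TRUE	NA	NA	NA
ZNF462	-1	TRUE	NA	NA	NA
ADPGK	1	TRUE	NA	NA	NA
BTRC	1	TRUE	-1	rs10883618	A
CAMKMT	1	TRUE	NA	NA	NA
DIPK1A	1	TRUE	NA	NA	NA
E2F3	1	TRUE	NA	NA	NA
FOXP1	1	TRUE	NA	NA	NA
HTT	1	TRUE	NA	NA	NA
IGF2BP3	1	TRUE	NA	NA	NA
JMJD1C	1	TRUE	NA	NA	NA
LCORL	1	TRUE	-1	rs1472852	C
MLLT10	1	TRUE	NA	NA	NA
MTCH2	1	TRUE	-1	rs11039324	G
NCOA1	1	TRUE	NA	NA	NA
PIEZO1	1	TRUE	NA	NA	NA
TRIB1	1	TRUE	NA	NA	NA
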