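# Sarcopenia-panel genes whose skeletal-muscle (m. vastus lateralis) mRNA
# changes significantly (p < 0.05) after a single bout of resistance exercise:
# 10 upregulated, 16 downregulated.
# Transcription note: the source prints the downregulated list with
# "TRIB1 WWP2" run together as one token (15 printed tokens for a stated 16);
# both symbols are genes of the panel and are recorded here as two entries.
gene	exercise_response
ADCY3	up
E2F3	up
JMJD1C	up
JUND	up
MLN	up
MYO1C	up
PIEZO1	up
PPARD	up
SFMBT1	up
ZNF462	up
CDKAL1	down
CEP192	down
DLEU1	down
GADD45G	down
GBF1	down
GLCCI1	down
MAML3	down
MMS22L	down
NYAP2	down
SDCCAG8	down
SWT1	down
TRIB1	down
WWP2	down
XPO4	down
ZBTB38	down
ZNF420	down
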