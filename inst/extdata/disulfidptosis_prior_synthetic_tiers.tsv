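SLC7A11	validated
SLC3A2	validated
RPN1	validated
NCKAP1	validated
NUBPL	validated
NDUFA11	validated
LRPPRC	validated
OXSM	validated
NDUFS1	validated
GYS1	validated
G6PD	screened
PGD	screened
TKT	screened
TALDO1	screened
RPIA	screened
SLC2A1	screened
SLC2A3	screened
PFKL	screened
PFKM	screened
ALDOA	screened
GAPDH	screened
PGK1	screened
ENO1	screened
PKM	screened
LDHA	screened
ACTB	screened
ACTG1	screened
ACTN4	screened
FLNA	screened
FLNB	screened
MYH9	screened
MYH10	screened
MYH14	screened
MYL6	screened
TLN1	screened
CAPZB	screened
DSTN	deduced
CD2AP	deduced
INF2	deduced
WASF1	deduced
WASF2	deduced
WASF3	deduced
ABI1	deduced
ABI2	deduced
CYFIP1	deduced
CYFIP2	deduced
BRK1	deduced
RAC1	deduced
NCKAP1L	deduced
ACTR2	deduced
ACTR3	deduced
ARPC1B	deduced
ARPC2	deduced
ARPC3	deduced
ARPC4	deduced
ARPC5	deduced
CTTN	deduced
CFL1	deduced
CFL2	deduced
PFN1	deduced
TPM1	deduced
TPM3	deduced
TPM4	deduced
MYL12A	deduced
MYL12B	deduced
VCL	deduced
PXN	deduced
ZYX	deduced
TJP1	deduced
CDH2	deduced
ITGB1	deduced
ITGA3	deduced
FERMT2	deduced
PARVA	deduced
GCLC	deduced
GCLM	deduced
GSS	deduced
GPX1	deduced
TXN	deduced
TXNRD1	deduced
PRDX1	deduced
NFE2L2	deduced
KEAP1	deduced
SLC1A5	deduced
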