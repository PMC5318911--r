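gene	mirna	pearson_r
APC	hsa-miR-27a-3p	-0.1593
ATN1	hsa-miR-27a-3p	0.0434
BCL2	hsa-miR-29c-3p	-0.3821
CASP3	hsa-miR-30d-5p	0.2322
CDC42	hsa-miR-29c-3p	-0.0699
CDKN1A	hsa-miR-20b-5p	0.0252
CDV3	hsa-miR-29c-3p	0.3099
CEP68	hsa-miR-29c-3p	-0.6030
COL1A1	hsa-miR-29c-3p	-0.2175
COL1A2	hsa-miR-29c-3p	-0.2585
COPS7A	hsa-miR-30d-5p	-0.0419
CRIM1	hsa-miR-20b-5p	-0.1046
DICER1	hsa-miR-29c-3p	0.0437
FAM126B	hsa-miR-29c-3p	-0.0549
FAM21C	hsa-miR-27a-3p	-0.1660
GNB4	hsa-miR-29c-3p	-0.5777
HIF1A	hsa-miR-20b-5p	-0.2779
HIPK2	hsa-miR-27a-3p	-0.2292
IGF1	hsa-miR-27a-3p	-0.5196
KCTD14	hsa-miR-27a-3p	0.0652
MUC17	hsa-miR-20b-5p	0.0073
PDS5B	hsa-miR-27a-3p	0.2830
PHB	hsa-miR-27a-3p	0.4625
PPARG	hsa-miR-20b-5p	0.3125
RMND5A	hsa-miR-27a-3p	-0.2091
SPIN4	hsa-miR-29c-3p	0.3670
STAT3	hsa-miR-20b-5p	-0.3452
TP53	hsa-miR-27a-3p	0.1937
TP53	hsa-miR-30d-5p	-0.0408
ZNF778	hsa-miR-27a-3p	0.2113
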