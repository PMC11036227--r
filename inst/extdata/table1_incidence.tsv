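disease	gene	n_cases	incidence_n	carrier_n
cblC-MMA	MMACHC	5	5920	52
PCD	SLC22A5	5	5920	63
PKU	PAH	3	9867	42
SCADD	ACADS	2	14801	127
IBD	ACAD8	2	14801	211
NICCD	SLC25A13	1	29601	55
MCAD	ACADM	1	29601	251
CPTII	CPT2	1	29601	580
cblA-MMA	MMAA	1	29601	1139
MSUD	DBT	1	29601	1480
MADD	ETFA	1	29601	NA
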