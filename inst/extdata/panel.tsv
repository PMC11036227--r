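gene	inheritance	in_panel	disease	group
ACAD8	AR	TRUE	IBD	OA
ACADM	AR	TRUE	MCAD	FAOD
ACADS	AR	TRUE	SCADD	FAOD
ACADSB	AR	TRUE	2MBG	OA
CPT2	AR	TRUE	CPTII	FAOD
DBT	AR	TRUE	MSUD	AA
ETFA	AR	FALSE	MADD	FAOD
MMAA	AR	TRUE	cblA-MMA	OA
MMACHC	AR	TRUE	cblC-MMA	OA
OTC	XL	TRUE	OTCD	AA
PAH	AR	TRUE	PKU	AA
PRODH	AR	TRUE	HPRO	AA
SLC22A5	AR	TRUE	PCD	FAOD
SLC25A13	AR	TRUE	NICCD	AA
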