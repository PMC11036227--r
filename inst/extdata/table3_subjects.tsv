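subject_id	sex	ngs_call	msms_call	disorder	confirmed
P1	M	positive	positive	cblA-MMA	TRUE
P2	M	positive	positive	cblC-MMA	TRUE
P3	M	positive	positive	cblC-MMA	TRUE
P4	M	positive	positive	cblC-MMA	TRUE
P5	F	positive	negative	cblC-MMA	TRUE
P6	M	positive	positive	cblC-MMA	TRUE
P7	M	positive	positive	PKU	TRUE
P8	M	positive	positive	PKU	TRUE
P9	M	positive	positive	PKU	TRUE
P10	M	positive	positive	PCD	TRUE
P11	M	positive	positive	PCD	TRUE
P12	M	positive	positive	PCD	TRUE
P13	M	positive	positive	PCD	TRUE
P14	M	positive	positive	SCADD	TRUE
P15	M	positive	positive	IBD	TRUE
P16	M	positive	positive	MCAD	TRUE
P17	M	positive	negative	NICCD	TRUE
P18	M	negative	positive	MSUD	TRUE
P19	M	negative	positive	IBD	TRUE
P20	M	negative	positive	SCADD	TRUE
P21	M	negative	positive	PCD	TRUE
P22	M	negative	positive	CPTII	TRUE
P23	M	negative	positive	MADD	TRUE
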