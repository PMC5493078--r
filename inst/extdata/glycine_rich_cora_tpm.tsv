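label	tag	antisense	NAS	NAT	AS	AT
NAT7	CATGATGCTCATTCAAAGTAATAAGT	FALSE	0	94.47	0	0
NAT46	CATGATGCAAATTCAAAGTAATAAGT	FALSE	0	14.21	0	0
A1=T1	CATGAATCTTTTGAGGTTATGTATTA	FALSE	0	0.25	0	2268.51
A7=T4	CATGAATCTTGTATGGTTATGTATTA	FALSE	0	1.25	0	158.50
A8=T28	CATGTATATGTAGTAACTAGTTTAAT	FALSE	0.47	0.25	3.17	61.86
A12	CATGCACGTATTAAGTGTAATATAAA	FALSE	8.77	98.21	668.21	6150.45
A18=T25	CATGGTTATAGCCTCCTCCTCCACCA	TRUE	0	0	0.93	20.06
A20	CATGTGTAATTTATCAAATATCATCA	FALSE	19.43	68.54	537.55	2591.53
A22	CATGGTTTTTCTCATTTCATCAGTGG	FALSE	0.24	0.25	1.31	15.38
A25=T26	CATGATGATATAATCAGTTACCATTG	TRUE	0	0	0.75	15.38
A32	CATGAATAAATAGAGTTGGATGTTGA	FALSE	0.24	2.24	6.16	43.80
A35	CATGGCCAATAGGCCAAGGATGAGGA	TRUE	0.24	1.25	2.99	21.40
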