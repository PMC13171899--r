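gene	allele	chrom	pos	ref	alt	function	activity
CYP2B6	*1					normal
CYP2B6	*6	CYP2B6	1761	G	T	decreased
CYP2B6	*6	CYP2B6	2511	A	G	decreased
CYP2B6	*4	CYP2B6	2021	A	G	increased
CYP2C19	*1					normal
CYP2C19	*2	CYP2C19	2261	G	A	no
CYP2C19	*3	CYP2C19	1511	G	A	no
CYP2C19	*17	CYP2C19	1261	C	T	increased
CYP2C9	*1					normal	1
CYP2C9	*2	CYP2C9	1271	C	T	decreased	0.5
CYP2C9	*3	CYP2C9	2531	A	C	no	0
CYP2D6	*1					normal	1
CYP2D6	*2	CYP2D6	1281	C	T	normal	1
CYP2D6	*4	CYP2D6	1791	G	A	no	0
CYP2D6	*10	CYP2D6	1031	C	T	decreased	0.25
CYP2D6	*41	CYP2D6	2291	G	A	decreased	0.5
CYP3A5	*1					normal
CYP3A5	*3	CYP3A5	1499	A	G	no
CYP3A5	*6	CYP3A5	2261	G	A	no
DPYD	*1					normal
DPYD	*2A	DPYD	4261	G	A	no
DPYD	HapB3	DPYD	2761	C	T	decreased
G6PD	B					normal
G6PD	A-	G6PD	1041	C	T	no
G6PD	A-	G6PD	1291	G	A	no
G6PD	Mediterranean	G6PD	2031	C	T	no
NUDT15	*1					normal
NUDT15	*3	NUDT15	1311	C	T	no
TPMT	*1					normal
TPMT	*3A	TPMT	2271	G	A	no
TPMT	*3A	TPMT	2771	A	G	no
TPMT	*3C	TPMT	2771	A	G	no
SLCO1B1	*1					normal
SLCO1B1	*5	SLCO1B1	2041	T	C	decreased
SLCO1B1	*14	SLCO1B1	1551	A	G	increased
VKORC1	wildtype					normal
VKORC1	rs9923231	VKORC1	951	G	A	decreased
ABCG2	wildtype					normal
ABCG2	rs2231142	ABCG2	2011	C	A	decreased
COMT	Val					normal
COMT	Met	COMT	1761	G	A	decreased
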