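drug	gene	phenotype	n
amitriptyline	CYP2C19	RM	3
amitriptyline	CYP2C19	NM	1
amitriptyline	CYP2C19	IM	6
(es)citalopram	CYP2C19	RM	4
(es)citalopram	CYP2C19	NM	3
(es)citalopram	CYP2C19	IM	3
clopidogrel	CYP2C19	RM	1
clopidogrel	CYP2C19	NM	1
clopidogrel	CYP2C19	IM	1
doxepin	CYP2C19	UM	1
doxepin	CYP2C19	IM	1
omeprazole	CYP2C19	RM	4
omeprazole	CYP2C19	NM	6
omeprazole	CYP2C19	IM	6
pantoprazole	CYP2C19	UM	6
pantoprazole	CYP2C19	RM	22
pantoprazole	CYP2C19	NM	24
pantoprazole	CYP2C19	IM	21
pantoprazole	CYP2C19	PM	4
sertraline	CYP2C19	RM	2
sertraline	CYP2C19	NM	7
sertraline	CYP2C19	IM	4
trimipramine	CYP2C19	RM	2
trimipramine	CYP2C19	IM	2
voriconazole	CYP2C19	NM	1
voriconazole	CYP2C19	IM	1
amitriptyline	CYP2D6	UM	1
amitriptyline	CYP2D6	NM	4
amitriptyline	CYP2D6	IM	4
amitriptyline	CYP2D6	indeterminate	1
aripiprazole	CYP2D6	NM	3
aripiprazole	CYP2D6	IM	1
aripiprazole	CYP2D6	PM	1
aripiprazole	CYP2D6	indeterminate	1
atomoxetine	CYP2D6	NM	3
doxepin	CYP2D6	NM	1
doxepin	CYP2D6	IM	1
flecainide	CYP2D6	NM	1
flecainide	CYP2D6	IM	3
haloperidol	CYP2D6	NM	2
haloperidol	CYP2D6	IM	1
metoprolol	CYP2D6	UM	1
metoprolol	CYP2D6	NM	11
metoprolol	CYP2D6	IM	7
metoprolol	CYP2D6	indeterminate	1
ondansetron	CYP2D6	UM	1
ondansetron	CYP2D6	NM	6
ondansetron	CYP2D6	IM	4
ondansetron	CYP2D6	PM	2
propafenone	CYP2D6	NM	1
risperidone	CYP2D6	NM	11
risperidone	CYP2D6	IM	10
risperidone	CYP2D6	PM	1
risperidone	CYP2D6	indeterminate	2
tamoxifen	CYP2D6	IM	2
tramadol	CYP2D6	NM	6
tramadol	CYP2D6	IM	2
trimipramine	CYP2D6	NM	1
trimipramine	CYP2D6	IM	3
venlafaxine	CYP2D6	NM	2
venlafaxine	CYP2D6	IM	3
zuclopenthixol	CYP2D6	PM	1
celecoxib	CYP2C9	NM	2
celecoxib	CYP2C9	IM (AS 1.5)	3
celecoxib	CYP2C9	IM (AS 1)	1
ibuprofen	CYP2C9	NM	53
ibuprofen	CYP2C9	IM (AS 1.5)	15
ibuprofen	CYP2C9	IM (AS 1)	10
ibuprofen	CYP2C9	PM	1
phenytoin	CYP2C9	NM	1
sertraline	CYP2B6	NM	6
sertraline	CYP2B6	IM	4
sertraline	CYP2B6	PM	2
sertraline	CYP2B6	indeterminate	1
atorvastatin	SLCO1B1	increased function	1
atorvastatin	SLCO1B1	normal function	10
atorvastatin	SLCO1B1	decreased function	1
atorvastatin	SLCO1B1	poor function	1
lovastatin	SLCO1B1	normal function	1
pravastatin	SLCO1B1	normal function	1
rosuvastatin	SLCO1B1	normal function	1
rosuvastatin	SLCO1B1	poor function	2
simvastatin	SLCO1B1	increased function	1
simvastatin	SLCO1B1	normal function	5
simvastatin	SLCO1B1	decreased function	2
allopurinol	ABCG2	wildtype	4
rosuvastatin	ABCG2	wildtype	2
rosuvastatin	ABCG2	rs2231142 heterozygous	1
tacrolimus	CYP3A5	PM	4
fluorouracil	DPYD	NM	1
dapsone	G6PD	normal	2
nitrofurantoin	G6PD	normal	1
azathioprine	NUDT15	NM	3
mercaptopurine	NUDT15	NM	5
thioguanine	NUDT15	NM	3
azathioprine	TPMT	NM	3
mercaptopurine	TPMT	NM	5
thioguanine	TPMT	NM	3
phenprocoumon	VKORC1	wildtype	1
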