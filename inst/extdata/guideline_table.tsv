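drug	gene	phenotype	recommendation	other_actionable
amitriptyline	CYP2C19	UM	dosing_alternate_drug	NA
amitriptyline	CYP2C19	RM	dosing_alternate_drug	NA
amitriptyline	CYP2C19	NM	no_action	NA
amitriptyline	CYP2C19	IM	no_action	NA
amitriptyline	CYP2C19	PM	dosing_alternate_drug	NA
(es)citalopram	CYP2C19	UM	dosing_alternate_drug	NA
(es)citalopram	CYP2C19	RM	dosing_alternate_drug	NA
(es)citalopram	CYP2C19	NM	no_action	NA
(es)citalopram	CYP2C19	IM	dosing	NA
(es)citalopram	CYP2C19	PM	dosing_alternate_drug	NA
clopidogrel	CYP2C19	UM	no_action	NA
clopidogrel	CYP2C19	RM	no_action	NA
clopidogrel	CYP2C19	NM	no_action	NA
clopidogrel	CYP2C19	IM	alternate_drug	NA
clopidogrel	CYP2C19	PM	alternate_drug	NA
doxepin	CYP2C19	UM	dosing_alternate_drug	NA
doxepin	CYP2C19	RM	dosing_alternate_drug	NA
doxepin	CYP2C19	NM	no_action	NA
doxepin	CYP2C19	IM	no_action	NA
doxepin	CYP2C19	PM	dosing_alternate_drug	NA
omeprazole	CYP2C19	UM	dosing	NA
omeprazole	CYP2C19	RM	dosing	NA
omeprazole	CYP2C19	NM	no_action	NA
omeprazole	CYP2C19	IM	dosing	NA
omeprazole	CYP2C19	PM	dosing	NA
pantoprazole	CYP2C19	UM	dosing	NA
pantoprazole	CYP2C19	RM	dosing	NA
pantoprazole	CYP2C19	NM	dosing	NA
pantoprazole	CYP2C19	IM	dosing	NA
pantoprazole	CYP2C19	PM	dosing	NA
sertraline	CYP2C19	UM	no_action	NA
sertraline	CYP2C19	RM	no_action	NA
sertraline	CYP2C19	NM	no_action	NA
sertraline	CYP2C19	IM	dosing	NA
sertraline	CYP2C19	PM	dosing_alternate_drug	NA
trimipramine	CYP2C19	UM	no_action	NA
trimipramine	CYP2C19	RM	dosing_alternate_drug	NA
trimipramine	CYP2C19	NM	no_action	NA
trimipramine	CYP2C19	IM	no_action	NA
trimipramine	CYP2C19	PM	dosing_alternate_drug	NA
voriconazole	CYP2C19	UM	alternate_drug	NA
voriconazole	CYP2C19	RM	alternate_drug	NA
voriconazole	CYP2C19	NM	no_action	NA
voriconazole	CYP2C19	IM	no_action	NA
voriconazole	CYP2C19	PM	alternate_drug	NA
amitriptyline	CYP2D6	UM	alternate_drug	NA
amitriptyline	CYP2D6	NM	no_action	NA
amitriptyline	CYP2D6	IM	dosing	NA
amitriptyline	CYP2D6	PM	alternate_drug	NA
aripiprazole	CYP2D6	UM	alternate_drug	NA
aripiprazole	CYP2D6	NM	no_action	NA
aripiprazole	CYP2D6	IM	dosing	NA
aripiprazole	CYP2D6	PM	alternate_drug	NA
atomoxetine	CYP2D6	UM	dosing	NA
atomoxetine	CYP2D6	NM	dosing	NA
atomoxetine	CYP2D6	IM	dosing	NA
atomoxetine	CYP2D6	PM	dosing	NA
doxepin	CYP2D6	UM	alternate_drug	NA
doxepin	CYP2D6	NM	no_action	NA
doxepin	CYP2D6	IM	dosing	NA
doxepin	CYP2D6	PM	alternate_drug	NA
flecainide	CYP2D6	UM	alternate_drug	NA
flecainide	CYP2D6	NM	no_action	NA
flecainide	CYP2D6	IM	dosing	NA
flecainide	CYP2D6	PM	alternate_drug	NA
haloperidol	CYP2D6	UM	dosing_alternate_drug	NA
haloperidol	CYP2D6	NM	no_action	NA
haloperidol	CYP2D6	IM	no_action	NA
haloperidol	CYP2D6	PM	dosing	NA
metoprolol	CYP2D6	UM	no_action	NA
metoprolol	CYP2D6	NM	no_action	NA
metoprolol	CYP2D6	IM	no_action	NA
metoprolol	CYP2D6	PM	alternate_drug	NA
ondansetron	CYP2D6	UM	alternate_drug	NA
ondansetron	CYP2D6	NM	no_action	NA
ondansetron	CYP2D6	IM	no_action	NA
ondansetron	CYP2D6	PM	no_action	NA
propafenone	CYP2D6	UM	dosing_alternate_drug	NA
propafenone	CYP2D6	NM	no_action	NA
propafenone	CYP2D6	IM	dosing_alternate_drug	NA
propafenone	CYP2D6	PM	dosing	NA
risperidone	CYP2D6	UM	dosing_alternate_drug	NA
risperidone	CYP2D6	NM	no_action	NA
risperidone	CYP2D6	IM	no_action	NA
risperidone	CYP2D6	PM	dosing	NA
tamoxifen	CYP2D6	UM	no_action	NA
tamoxifen	CYP2D6	NM	no_action	NA
tamoxifen	CYP2D6	IM	dosing_alternate_drug	NA
tamoxifen	CYP2D6	PM	dosing_alternate_drug	NA
tramadol	CYP2D6	UM	alternate_drug	NA
tramadol	CYP2D6	NM	no_action	NA
tramadol	CYP2D6	IM	other	TRUE
tramadol	CYP2D6	PM	alternate_drug	NA
trimipramine	CYP2D6	UM	dosing_alternate_drug	NA
trimipramine	CYP2D6	NM	no_action	NA
trimipramine	CYP2D6	IM	dosing	NA
trimipramine	CYP2D6	PM	dosing_alternate_drug	NA
venlafaxine	CYP2D6	UM	no_action	NA
venlafaxine	CYP2D6	NM	no_action	NA
venlafaxine	CYP2D6	IM	no_action	NA
venlafaxine	CYP2D6	PM	alternate_drug	NA
zuclopenthixol	CYP2D6	UM	dosing	NA
zuclopenthixol	CYP2D6	NM	no_action	NA
zuclopenthixol	CYP2D6	IM	dosing	NA
zuclopenthixol	CYP2D6	PM	dosing	NA
celecoxib	CYP2C9	NM	no_action	NA
celecoxib	CYP2C9	IM (AS 1.5)	no_action	NA
celecoxib	CYP2C9	IM (AS 1)	dosing	NA
celecoxib	CYP2C9	PM	dosing	NA
ibuprofen	CYP2C9	NM	no_action	NA
ibuprofen	CYP2C9	IM (AS 1.5)	no_action	NA
ibuprofen	CYP2C9	IM (AS 1)	dosing	NA
ibuprofen	CYP2C9	PM	dosing_alternate_drug	NA
phenytoin	CYP2C9	NM	no_action	NA
phenytoin	CYP2C9	IM (AS 1.5)	no_action	NA
phenytoin	CYP2C9	IM (AS 1)	dosing	NA
phenytoin	CYP2C9	PM	dosing	NA
sertraline	CYP2B6	UM	no_action	NA
sertraline	CYP2B6	RM	no_action	NA
sertraline	CYP2B6	NM	no_action	NA
sertraline	CYP2B6	IM	dosing	NA
sertraline	CYP2B6	PM	dosing_alternate_drug	NA
atorvastatin	SLCO1B1	increased function	no_action	NA
atorvastatin	SLCO1B1	normal function	no_action	NA
atorvastatin	SLCO1B1	decreased function	dosing	NA
atorvastatin	SLCO1B1	poor function	dosing_alternate_drug	NA
lovastatin	SLCO1B1	increased function	no_action	NA
lovastatin	SLCO1B1	normal function	no_action	NA
lovastatin	SLCO1B1	decreased function	dosing_alternate_drug	NA
lovastatin	SLCO1B1	poor function	alternate_drug	NA
pravastatin	SLCO1B1	increased function	no_action	NA
pravastatin	SLCO1B1	normal function	no_action	NA
pravastatin	SLCO1B1	decreased function	other	FALSE
pravastatin	SLCO1B1	poor function	dosing_alternate_drug	NA
rosuvastatin	SLCO1B1	increased function	no_action	NA
rosuvastatin	SLCO1B1	normal function	no_action	NA
rosuvastatin	SLCO1B1	decreased function	other	FALSE
rosuvastatin	SLCO1B1	poor function	dosing	NA
simvastatin	SLCO1B1	increased function	no_action	NA
simvastatin	SLCO1B1	normal function	no_action	NA
simvastatin	SLCO1B1	decreased function	dosing_alternate_drug	NA
simvastatin	SLCO1B1	poor function	alternate_drug	NA
allopurinol	ABCG2	wildtype	no_action	NA
allopurinol	ABCG2	rs2231142 heterozygous	dosing	NA
allopurinol	ABCG2	rs2231142 homozygous	dosing	NA
rosuvastatin	ABCG2	wildtype	no_action	NA
rosuvastatin	ABCG2	rs2231142 heterozygous	no_action	NA
rosuvastatin	ABCG2	rs2231142 homozygous	dosing_alternate_drug	NA
tacrolimus	CYP3A5	NM	dosing	NA
tacrolimus	CYP3A5	IM	dosing	NA
tacrolimus	CYP3A5	PM	no_action	NA
fluorouracil	DPYD	NM	no_action	NA
fluorouracil	DPYD	IM	dosing	NA
fluorouracil	DPYD	PM	alternate_drug	NA
dapsone	G6PD	normal	no_action	NA
dapsone	G6PD	variable	other	FALSE
dapsone	G6PD	deficient	alternate_drug	NA
nitrofurantoin	G6PD	normal	no_action	NA
nitrofurantoin	G6PD	variable	other	FALSE
nitrofurantoin	G6PD	deficient	other	FALSE
azathioprine	NUDT15	NM	no_action	NA
azathioprine	NUDT15	IM	dosing	NA
azathioprine	NUDT15	PM	dosing_alternate_drug	NA
mercaptopurine	NUDT15	NM	no_action	NA
mercaptopurine	NUDT15	IM	dosing	NA
mercaptopurine	NUDT15	PM	dosing_alternate_drug	NA
thioguanine	NUDT15	NM	no_action	NA
thioguanine	NUDT15	IM	dosing	NA
thioguanine	NUDT15	PM	dosing_alternate_drug	NA
azathioprine	TPMT	NM	no_action	NA
azathioprine	TPMT	IM	dosing	NA
azathioprine	TPMT	PM	dosing_alternate_drug	NA
mercaptopurine	TPMT	NM	no_action	NA
mercaptopurine	TPMT	IM	dosing	NA
mercaptopurine	TPMT	PM	dosing_alternate_drug	NA
thioguanine	TPMT	NM	no_action	NA
thioguanine	TPMT	IM	dosing	NA
thioguanine	TPMT	PM	dosing_alternate_drug	NA
phenprocoumon	VKORC1	wildtype	no_action	NA
phenprocoumon	VKORC1	rs9923231 heterozygous	no_action	NA
phenprocoumon	VKORC1	rs9923231 homozygous	dosing	NA
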