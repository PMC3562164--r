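abbreviation	name	starting_concentration_uM	ppc_uM	components
CIS	cisplatin	16.7	8.33	CIS
5FU	5-fluorouracil	3840	117	5FU
CPT	irinotecan	295		CPT
SN38	SN-38	102	0.051	SN38
DTX	docetaxel	116	2.32	DTX
PXL	paclitaxel	70.3	5.86	PXL
MTX	methotrexate	55	33	MTX
DXR	doxorubicin	172	0.62	DXR
EPI	epirubicin	172	17.2	EPI
EPS	etoposide	340	16.9	EPS
GEM	gemcitabine	3340	73.4	GEM
OXP	oxaliplatin	126	2.27	OXP
VIN	vinorelbin	93	0.93	VIN
LEU	leucovorin	59	6.84	LEU
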