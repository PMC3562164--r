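drug	logistic	hyperbolic	straight	exponential	linear	noise_dominant
CIS	9	11	0	1	3	5
5FU	5	7	3	0	3	11
CPT	10	3	1	0	1	5
SN38	11	0	0	0	2	8
DTX	18	3	1	1	0	5
PXL	22	1	1	0	1	4
OXP	3	0	0	0	0	0
EPS	3	1	0	0	0	0
GEM	1	1	0	0	1	0
5FU+LEU	0	2	0	0	1	0
CIS+5FU	4	3	1	0	0	1
MTX	3	0	0	0	1	3
5FU+MTX	1	0	1	0	0	0
EPI	0	0	1	0	0	0
CBP	0	1	0	0	0	0
5FU+DTX	1	0	0	0	0	0
5FU+SN38	1	0	0	0	0	0
DXR	1	0	0	0	0	0
VIN	0	0	0	0	0	1
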