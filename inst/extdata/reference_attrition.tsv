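source	n_total	n_sufficient	n_analyzed	n_curves	excl_low_viability	excl_fungal	excl_bacterial
ascites	22	16	15	110	1	0	0
solid	21	18	14	83	1	2	1
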