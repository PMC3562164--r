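endpoint	Up	Stable	Down
CEA	6	3	4
CA19-9	2	7	4
ascites_volume	2	3	8
diet	8	0	5
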