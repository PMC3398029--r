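ray	combination	clones	hybrids	none	shoots	plantlets
None	WB	57	8	6	2	0
UV	WB30	82	14	11	3	0
UV	WB60	140	41	32	7	2
UV	WB120	142	36	29	7	0
UV	WB180	102	14	11	3	0
Gamma	WB3K	55	15	12	3	0
Gamma	WB5K	58	24	20	4	0
Gamma	WB7K	29	11	9	2	0
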