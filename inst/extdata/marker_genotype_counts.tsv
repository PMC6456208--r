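marker	male_aa	male_ab	male_bb	female_mono_aa	female_mono_ab	female_mono_bb
SP_0073	0	104	0	108	0	0
SP_0079	0	104	0	108	0	0
SP_0080	0	104	0	108	0	0
SP_0081	0	104	0	107	1	0
SP_0086	0	104	0	108	0	0
SP_0088	0	104	0	107	1	0
SP_0089	102	2	0	108	0	0
SP_0090	0	104	0	11	97	0
SP_0091	0	104	0	108	0	0
SP_0093	100	4	0	108	0	0
SP_0097	93	11	0	107	1	0
SP_0100	0	104	0	108	0	0
SP_0152	68	34	2	107	0	1
SP_0158	66	38	0	105	3	0
SP_0166	6	98	0	4	104	0
SP_0259	0	104	0	108	0	0
SP_0260	0	103	1	108	0	0
SP_0261	0	104	0	108	0	0
SP_0262	103	1	0	108	0	0
SP_0264	0	104	0	108	0	0
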