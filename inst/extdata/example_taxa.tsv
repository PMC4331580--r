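sample	Geobacter	Dechloromonas	Clostridium	Pseudomonas	Solibacillus	Bacillus	Other
NF_FER_C13_F5	1192	571	305	52	205	154	1511
NF_FER_C13_F6	1238	567	283	58	218	157	1469
NF_FER_C13_F7	1261	549	297	65	193	155	1470
NF_FER_C12_F5	99	73	137	68	41	82	3490
NF_FER_C12_F6	79	88	130	67	44	72	3510
NF_FER_C12_F7	88	73	124	66	36	67	3536
NF_GOE_C13_F5	464	72	198	206	45	92	2913
NF_GOE_C13_F6	445	77	217	186	48	62	2955
NF_GOE_C13_F7	449	77	204	184	28	76	2972
NF_GOE_C12_F5	112	86	128	72	37	74	3481
NF_GOE_C12_F6	94	88	111	54	30	75	3538
NF_GOE_C12_F7	107	69	124	58	36	86	3510
NF_CTR_C13_F5	88	78	119	50	46	70	3539
NF_CTR_C13_F6	90	93	133	53	36	83	3502
NF_CTR_C13_F7	97	88	113	54	46	70	3522
NF_CTR_C12_F5	79	64	124	67	44	62	3550
NF_CTR_C12_F6	101	72	134	47	45	65	3526
NF_CTR_C12_F7	117	81	108	83	40	62	3499
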