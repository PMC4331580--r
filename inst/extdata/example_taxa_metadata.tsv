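sample	soil	amendment	isotope	fraction
NF_FER_C13_F5	NF	FER	C13	5
NF_FER_C13_F6	NF	FER	C13	6
NF_FER_C13_F7	NF	FER	C13	7
NF_FER_C12_F5	NF	FER	C12	5
NF_FER_C12_F6	NF	FER	C12	6
NF_FER_C12_F7	NF	FER	C12	7
NF_GOE_C13_F5	NF	GOE	C13	5
NF_GOE_C13_F6	NF	GOE	C13	6
NF_GOE_C13_F7	NF	GOE	C13	7
NF_GOE_C12_F5	NF	GOE	C12	5
NF_GOE_C12_F6	NF	GOE	C12	6
NF_GOE_C12_F7	NF	GOE	C12	7
NF_CTR_C13_F5	NF	CTR	C13	5
NF_CTR_C13_F6	NF	CTR	C13	6
NF_CTR_C13_F7	NF	CTR	C13	7
NF_CTR_C12_F5	NF	CTR	C12	5
NF_CTR_C12_F6	NF	CTR	C12	6
NF_CTR_C12_F7	NF	CTR	C12	7
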