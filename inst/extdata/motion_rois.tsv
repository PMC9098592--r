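name	x	y	z	radius_mm
aINS_L	-36	24	2	10
aINS_R	36	24	2	10
EBA_L	-46	-75	-4	10
EBA_R	47	-71	-4	10
FBA_L	-38	-38	-27	10
FBA_R	43	-43	-28	10
FFG_L	-42	-56	-14	10
FFG_R	42	-56	-14	10
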