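signature	gene
pro_inflammatory	IL1B
pro_inflammatory	IL6
pro_inflammatory	TNF
pro_inflammatory	IL12A
pro_inflammatory	IL23A
pro_inflammatory	CXCL9
pro_inflammatory	CXCL10
pro_inflammatory	CCL5
anti_inflammatory	IL10
anti_inflammatory	TGFB1
anti_inflammatory	CCL22
anti_inflammatory	CCL17
anti_inflammatory	IL1RN
anti_inflammatory	VEGFA
anti_inflammatory	MMP9
m1_polarization	NOS2
m1_polarization	CD80
m1_polarization	CD86
m1_polarization	FCGR1A
m1_polarization	CXCL11
m1_polarization	SOCS3
m1_polarization	IRF5
m2_polarization	CD163
m2_polarization	MRC1
m2_polarization	MARCO
m2_polarization	CSF1R
m2_polarization	MSR1
m2_polarization	IL4R
m2_polarization	STAB1
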