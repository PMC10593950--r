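item	count	sample_n	percent_printed	digits
voices	1918	119947	1.6	1
visions	3696	119947	3	0
conspiracies	724	119947	0.60	2
communications	652	119947	0.54	2
sex_female	67432	119947	56	0
distress	2046	119947	1.76	2
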