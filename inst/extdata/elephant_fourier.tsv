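k	x_cos	x_sin	y_cos	y_sin
1	-60	-30	0	-50
2	0	8	0	-18
3	0	-10	-12	0
5	0	0	14	0
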