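category	None	Stage	Trt	Stage+Trt	Stage*Trt
None	855	131	46	40	26
Stage	60	4	9	15	19
Trt	13	4	3	3	0
Stage+Trt	4	0	0	1	2
Stage*Trt	26	6	6	6	9
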