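variable	level	no_relapse	relapse
er	Negative	160	97
er	Positive	617	346
node	Negative	629	340
node	Positive	94	93
grade	1	133	36
grade	2	221	173
grade	3	158	116
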