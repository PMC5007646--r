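# toy interaction network, unit-scale confidence scores
A	B	0.95
A	C	0.92
B	C	0.99
B	D	0.91
C	E	0.93
D	E	0.96
E	F	0.94
F	G	0.97
B	A	0.95
C	E	0.93
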