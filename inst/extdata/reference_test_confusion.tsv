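72	8	9	0
10	69	8	3
13	5	45	1
0	2	1	21
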