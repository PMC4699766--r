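z_Gy	probability
0.05	0.35
0.1	0.3
0.2	0.2
0.35	0.1
0.6	0.05
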