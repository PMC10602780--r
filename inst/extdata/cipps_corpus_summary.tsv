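speaker	tokens	utterances
A	2563	619
B	30021	4204
C	10409	1552
D	1277	332
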