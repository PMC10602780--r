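speaker	n_simple	n_complex	n_stanza	n_with_top	n_with_apc
A	39	32	6	6	6
B	125	109	40	71	17
C	86	84	32	36	15
D	93	84	25	24	22
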