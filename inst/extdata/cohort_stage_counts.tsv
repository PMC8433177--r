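stage	n
N	31
F0	35
F1	30
F2	27
F3	8
F4	12
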