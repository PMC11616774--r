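# diamond: two equal shortest paths a -> d, through b and through c
targets, factors
a, 0
b, a
c, a
d, b | c
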