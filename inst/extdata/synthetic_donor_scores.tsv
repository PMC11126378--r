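ninemer	score
AAGGTAAGC	9.4
AGCGTCCAA	-6.23
CAGGTACGC	6.54
CACGTACAC	-11.07
ACAGTCACA	-11.54
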