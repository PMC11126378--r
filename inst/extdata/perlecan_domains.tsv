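domain_label	codon_start	codon_end
Domain IV	1695	3655
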