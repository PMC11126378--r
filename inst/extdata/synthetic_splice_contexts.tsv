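name	sequence	authentic_offset	exon_length_bp	authentic_score
c.7006+1G>A	CACACACACACACACACACACACACACACACACACACACACACACAAAGGTAAGCGTCCAAACACACACACACACACACACACACACACACACACACACA	50	136	9.4
c.11562+2T>G	CACACACACACACACACACACACACACACGTACACACACACACACACAGGTACGCACACACACACACACACACACACACACAGTCACACACACACACACA	50	110	6.54
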