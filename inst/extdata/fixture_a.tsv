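gene_id	s1	s2	s3	s4	s5	s6
g1	3	7	5	9	4	8
g2	1	2	6	4	5	3
g3	10	6	7	3	9	2
g4	2	8	3	7	6	5
g5	4	4	9	1	8	6
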