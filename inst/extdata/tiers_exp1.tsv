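min_tags	max_tags	ratio	background	combine
18	NA	2.0	6.0	or
16	17	2.5	4.0	and
14	15	3.6	4.0	and
13	13	9.0	8.0	and
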