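min_tags	max_tags	ratio	background	combine
53	NA	2.2	6.0	or
22	52	2.2	6.0	and
19	21	4.0	10.0	and
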