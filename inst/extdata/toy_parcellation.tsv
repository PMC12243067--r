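region_id	label	region_class	system	hemisphere
0	DMN_1	cortical	DMN	L
1	DMN_2	cortical	DMN	R
2	FPN_1	cortical	FPN	L
3	FPN_2	cortical	FPN	R
4	thalamus_1	subcortical	thalamus	L
5	thalamus_2	subcortical	thalamus	R
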