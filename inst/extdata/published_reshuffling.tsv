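population	intra_male	inter_male	total_male	intra_female	inter_female	sex_average
Catalan	0.0045	0.488	0.493	0	0.482	0.487
Swedish	0.0079	0.481	0.489	0	0.476	0.483
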