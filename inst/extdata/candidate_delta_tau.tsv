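strain_id	median_delta_tau
NCU08999	1.38
NCU04001	0.87
NCU03417	0.52
NCU01243	0.50
NCU01640	-0.51
NCU02307	-0.51
NCU04773	-0.56
NCU08443	-0.63
NCU09615	-0.63
NCU08042	-0.64
NCU03643	-0.66
NCU08652	-0.67
NCU07675	-0.67
NCU01154	-0.71
NCU09252	-0.71
NCU02413	-0.78
NCU10006	-0.83
NCU06213	-0.85
NCU00499	-0.91
NCU06140	-0.92
NCU08848	-1.04
NCU01238	-1.17
NCU06145	-1.88
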