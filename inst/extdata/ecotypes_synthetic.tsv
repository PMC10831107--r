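species	A_c	E_o
synthetic_low_Eo	10	-0.2
synthetic_medium_Eo	10	0.4
synthetic_high_Eo	10	1.0
synthetic_tolerant	20	0.4
synthetic_sensitive	5	0.4
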