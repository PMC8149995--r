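compound_id	name
C00001	H2O
C00002	ATP
C00003	NAD+
C00004	NADH
C00005	NADPH
C00006	NADP+
C00007	O2
C00008	ADP
C00009	Orthophosphate
C00011	CO2
C00080	H+
C05359	e-
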