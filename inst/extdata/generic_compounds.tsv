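compound_id	name
C00017	Protein
C00028	Acceptor
C00030	Reduced acceptor
C00039	DNA
C00046	RNA
C00069	Alcohol
C00071	Aldehyde
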