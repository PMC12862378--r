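amino_acid	pathway	dependent	independent
Asn	Q	AAU	AAC
Asp	Q	GAU	GAC
His	Q	CAU	CAC
Tyr	Q	UAU	UAC
Arg	Mnm	AGG	AGA
Gln	Mnm	CAG	CAA
Glu	Mnm	GAG	GAA
Gly	Mnm	GGG	GGA
Leu	Mnm	UUG	UUA
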