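gene	protein_name	effect	vLDX_ref	vMPH_ref
TAAR1	Trace amine-associated receptor 1	1	lit	-
SLC18A2	Synaptic vesicular amine transporter (VMAT2)	-1	lit	-
SLC6A3	Sodium-dependent dopamine transporter (DAT)	-1	lit	lit
SLC6A2	Sodium-dependent noradrenaline transporter (NET)	-1	lit	lit
SLC6A4	Sodium-dependent serotonin transporter (SERT)	-1	lit	-
MAOA	Amine oxidase (flavin-containing) A	-1	lit	-
MAOB	Amine oxidase (flavin-containing) B	-1	lit	-
HTR1A	5-hydroxytryptamine receptor 1A	1	-	lit
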