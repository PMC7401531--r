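name	category	accession	target_start	target_end	concentration_fM
IFNG	Pro-inflammatory cytokine	NM_174086.1	503	602	0
IL1B	Pro-inflammatory cytokine	NM_174093.1	331	430	0
IL6	Pro-inflammatory cytokine	NM_173923.2	293	392	0
IL8	Pro-inflammatory cytokine	NM_173925.2	278	377	0
TNFA	Pro-inflammatory cytokine	NM_173966.2	950	1049	0
IL10	Anti-inflammatory cytokine	NM_174088.1	145	244	0
AGTR2	Neuroactive ligand-receptor	XM_001249373.2	1206	1305	0
CRH	Neuroactive ligand-receptor	NM_001013400.1	443	542	0
NGF	Neuroactive ligand-receptor	NM_001099362.1	558	657	0
NOS1	Neuroactive ligand-receptor	XM_867630.5	2657	2756	0
PGHS2	Neuroactive ligand-receptor	NM_174445.2	881	980	0
TAC1	Neuroactive ligand-receptor	NM_174193.1	317	416	0
GAPDH	Reference	NM_001034034.1	213	312	0
GUSB	Reference	NM_001083436.1	1815	1914	0
YWHAZ	Reference	NM_174814.2	147	246	0
POS_A	Positive control		0	0	128
POS_B	Positive control		0	0	32
POS_C	Positive control		0	0	8
POS_D	Positive control		0	0	2
POS_E	Positive control		0	0	0.5
POS_F	Positive control		0	0	0.125
NEG_A	Negative control		0	0	0
NEG_B	Negative control		0	0	0
NEG_C	Negative control		0	0	0
NEG_D	Negative control		0	0	0
NEG_E	Negative control		0	0	0
NEG_F	Negative control		0	0	0
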