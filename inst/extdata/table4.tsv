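gene	compartment	cell_type	invivo_time	direction	annotation
PER1	blood	HMVEC	1	down	Circadian rhythm
SLC22A5	blood	HMVEC	1	down	Glucose transporter
TUBA1B	blood	HMVEC	1	up	Cell division
HIST1H3H	blood	HMVEC	6	up	Chromosomal structure
KPRP	blood	HMVEC	6	up	Keratinocyte differentiation
KRT79	blood	HMVEC	6	up	Epithelial cell integrity
MID1	blood	HMVEC	6	down	Adaptor protein
SHCBP1	blood	HMVEC	6	up	Cell proliferation
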