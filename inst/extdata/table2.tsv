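gene	compartment	cell_type	invivo_time	direction	annotation
CAND1	lung	HMVEC	1	down	Ubiquitin ligase regulation
HIST1H3F	lung	HMVEC	1	up	DNA structure
PPP1CC	lung	HMVEC	1	down	Phosphatase
SH2D1A	lung	HMVEC	1	down	T and B cell stimulation
SH3BP2	lung	HMVEC	1	down	Adaptor protein
SLC22A5	lung	HMVEC	1	down	Glucose transporter
TGM2	lung	HMVEC	1	down	Transglutaminase
HIST1H2AL	lung	HMVEC	6	up	DNA structure
TFEC	lung	HMVEC	6	down	Transcription factor
ABCE1	lung	HMVEC	12	down	Molecular transport
EIF4B	lung	HMVEC	12	down	Helicase
IKZF2	lung	HMVEC	12	down	Transcription factor
IL1R1	lung	HMVEC	12	down	Interleukin receptor
LXN	lung	HMVEC	12	down	Metallocarboxypeptidase inhibition
MID1	lung	HMVEC	12	up	Adaptor protein
NPM1	lung	HMVEC	12	down	ARF/p53 regulation
NUDT8	lung	HMVEC	12	up	Hydrolase
PIKFYVE	lung	HMVEC	12	down	Cytoskeletal functions, membrane trafficking, and receptor signaling
PPP1CC	lung	HMVEC	12	down	Phosphatase
SDHD	lung	HMVEC	12	down	Succinate oxidation
SLC30A7	lung	HMVEC	12	down	Zinc transporter
SMARCAD1	lung	HMVEC	12	down	Helicase
UBE2E1	lung	HMVEC	12	down	Ubiquitination
ZC3H13	lung	HMVEC	12	down	mRNA methylation
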