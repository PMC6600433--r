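gene	compartment	cell_type	invivo_time	direction	annotation
miR-183	lung	SAEC	1	up	
miR-204	lung	SAEC	6	up	
miR-335	lung	SAEC	12	up	
miR-204	lung	HMVEC	6	up	
miR-335	lung	HMVEC	12	up	
miR-26b	lung	HMVEC	12	up	
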