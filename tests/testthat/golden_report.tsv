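variant	variant_class	transcript_id	flags	verdict	primary_reason	pvs1_max_strength	confirmation_required	notes
chrT1-330-AA-A	frameshift	TXhomopolymer_frameshift_p_a	homopolymer:technical:likely_not_LoF	likely_not_LoF	homopolymer	pending_confirmation	TRUE	.
chrT2-569-TT-T	frameshift	TXhomopolymer_frameshift_m_a	homopolymer:technical:likely_not_LoF	likely_not_LoF	homopolymer	pending_confirmation	TRUE	.
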