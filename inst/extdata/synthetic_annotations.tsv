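id	is_vertebrate	has_signal_peptide	has_transmembrane	locations	uniprot_id
demo_pos_0001	yes	no	no	nucleus;cytosol	SYN00001
demo_pos_0002	yes	no	yes	GA	SYN00002
demo_pos_0003	yes	no	no	mitochondrion;other	SYN00003
demo_pos_0004	yes	no	no	other	SYN00004
demo_pos_0005	yes	no	no	nucleus	SYN00005
demo_pos_0006	yes	no	no	cytosol;other	SYN00006
demo_pos_0007	yes	no	no		SYN00007
demo_pos_0008	yes	no	no	other	SYN00008
demo_neg_0001	yes	yes	no		SYN00009
demo_neg_0002	yes	no	no	ER	SYN00010
demo_neg_0003	yes	no	no	other;cytosol	SYN00011
demo_neg_0004	yes	no	no	nucleus;GA	SYN00012
demo_neg_0005	yes	yes	no	cytosol	SYN00013
demo_neg_0006	yes	no	no	other	SYN00014
demo_neg_0007	yes	no	yes	GA	SYN00015
demo_neg_0008	yes	no	no	nucleus	SYN00016
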