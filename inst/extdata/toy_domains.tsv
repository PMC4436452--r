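protein_id	rank	sequence
prot1	1	MKVLYAAA
prot1	2	CHHKRDEQ
prot2	1	WWYYFFCC
prot3	1	ACDEFGHIK
prot3	2	LMNPQRST
prot3	3	VWYACDEF
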