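protein_id	go_terms
prot1	GO:0000003
prot2	GO:0000009
prot3	GO:0000002;GO:0000009
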