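>prot1 synthetic two-domain protein
MKVLYAAAGGCHHKRDEQNMKV
>prot2 synthetic single-domain protein
WWYYFFCCILMVAGPST
>prot3 synthetic three-domain protein
ACDEFGHIKLMNPQRSTVWYACDEF
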