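# two synthetic helical domains joined by a 19-residue disordered linker
CHAIN
DOMAIN domA synthetic_domain_A.pdb A
LINKER link1 19
DOMAIN domB synthetic_domain_B.pdb A
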