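# Region annotations for the toy complex: role -> chain + inclusive
# residue range (1-based, crystallographic numbering).
enzyme:    {chain: E, start: 130, end: 160}
ezh2_loop: {chain: E, start: 136, end: 142}
srm_helix: {chain: E, start: 143, end: 153}
reader:    {chain: R, start: 355, end: 370}
ligand:    {chain: L, start: 1, end: 1}
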