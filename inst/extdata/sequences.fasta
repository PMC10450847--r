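>aSyn alpha-synuclein, human, N=140
MDVFMKGLSKAKEGVVAAAEKTKQGVAEAAGKTKEGVLYVGSKTKEGVVHGVATVAEKTK
EQVTNVGGAVVTGVTAVAQKTVEGAGSIAAATGFVKKDQLGKNEEGAPQEGILEDMPVDP
DNEAYEMPSEEGYQDYEPEA
>A1 hnRNPA1 low-complexity domain construct (GS + residues 186-320 of isoform A1-A), N=137
GSMASASSSQRGRSGSGNFGGGRGGGFGGNDNFGRGGNFSGRGGFGGSRGGGGYGGSGDG
YNGFGNDGSNFGGGGSYNDFGNYNNQSSNFGPMKGGNFGGRSSGPYGGGGQYFAKPRNQG
GYGGSSSSSSYGSGRRF
>Hst5 histatin 5, human, N=24
DSHAKRHHGYKRKFHEKHHSHRGY
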