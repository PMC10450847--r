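scale,reversed,note
KYTJ820101,FALSE,Kyte-Doolittle hydropathy
HOPP,TRUE,Hopp-Woods hydrophilicity (higher = more hydrophilic)
EISEN,FALSE,Eisenberg consensus hydrophobicity
JANIN,FALSE,Janin buried/accessible free energy
FAUCH,FALSE,Fauchere-Pliska octanol partitioning
WIMLEY,FALSE,Wimley-White interface scale
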