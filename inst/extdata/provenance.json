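{
  "description": "Vendored residue parameter tables (stickiness lambda, van der Waals diameters sigma, formal charges, residue masses, His pKa) for the CALVADOS 1 and CALVADOS 2 model variants, reference sequences, experimental training metadata, and a curated subset of classic hydropathy scales.",
  "note": "hydropathy_scales_subset.csv is a 6-scale subset for examples; the full 70-scale prior set is not redistributed here.",
  "files": {
    "calvados1.csv": "de2e1fa174614e3f1831fc5004fb5b8d",
    "calvados2.csv": "434ba60c44463b832712eff3f184445d",
    "sequences.fasta": "d5d3a302fd34592f652887bacf45720e",
    "training_rg.csv": "2f7695c940eb2b3bd53ed1d772d498e9",
    "pre_training.csv": "57c716145ce9d5afa5a93ed02f8c73cd",
    "hydropathy_scales_subset.csv": "ccf880874aff53846acd278acb896d45",
    "scales_orientation.csv": "f7605924ba5ed97849d295a160a3921c"
  }
}
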