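# Packaged locus definitions: bordering (marker) genes anchoring each
# hematopoietic serine-protease locus across genomes.  Marker matching is
# case-insensitive and alias-resolved; edit a copy of this file to add
# assembly-specific names.
chymase:
  left_markers: [RIPK3, NYNRIN, CBLN3, SDR39U1]
  right_markers: [STXBP6]
  aliases:
    STXBP6: [RNF17]          # mouse rearrangement replaced STXBP6 with RNF17
    NYNRIN: [STOML1, LOXL1]  # ruminant rearrangement at the NYNRIN end
met_ase:
  left_markers: [POLRMT]
  right_markers: [FSTL3]
  center_markers: [FGF22, BSG, RNF126]
  aliases:
    FGF22: [FGF10-like, FBGF22, FGF-22-or-10-like]
    FSTL3: [FSTL-3]
fish_chymase:
  left_markers: [RABL3-like]
  right_markers: [CD276, ERCC1-like]
  aliases:
    RABL3-like: [rabl3, RABL3]
    ERCC1-like: [ERCC-1-like, ERCC1]
# The granzyme A/K (T cell tryptase) locus ships without default markers:
# its flanking genes are conserved but are shown only graphically in the
# source material, so the definition is left for the user to fill in.
granzyme_ak:
  left_markers: []
  right_markers: []
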