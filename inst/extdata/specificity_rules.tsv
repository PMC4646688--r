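pattern	type	label	tier	note
DGG	triplet	tryptase	exact	canonical tryptase triplet; Asp189 at the pocket bottom selects Arg/Lys P1
DGA	triplet	tryptase	exact	chicken complement factor D variant of DGG
GSD	triplet	tryptase	exact	PRSS57 (NSP-4) triplet; human enzyme shown to be tryptic
SGA	triplet	chymase	exact	canonical chymase triplet; small uncharged pocket accepts aromatic/large hydrophobic P1
SGG	triplet	chymase	putative	seen in non-canonical granzyme A/K relatives; likely chymase
SGN	triplet	chymase	putative	platypus enzyme closest to the placental SGA chymases
SGR	triplet	asp-ase	exact	granzyme B style; Arg226 selects acidic P1
TGR	triplet	asp-ase	exact	granzyme B style
AGR	triplet	asp-ase	exact	granzyme B style
SGK	triplet	asp-ase	putative	alligator cathepsin G-like; closest match is the granzyme B SGR
SGE	triplet	chymase_with_tryptase	exact	identical to human/chimpanzee cathepsin G position pattern
AGE	triplet	chymase_with_tryptase	exact	human cathepsin G; chymase with additional low tryptase activity
ASP	triplet	met-ase	exact	granzyme M style
AST	triplet	met-ase	exact	rat granzyme M variant
GVD	triplet	elastase	exact	neutrophil elastase / proteinase 3 style; small hydrophobic P1
GID	triplet	elastase	exact	neutrophil elastase / proteinase 3 style
NVA	triplet	elastase	exact	rodent alpha-chymase shown to be elastolytic
NVS	triplet	elastase	exact	hamster chymase II shown to be elastolytic
SVN	triplet	elastase	putative	platypus enzyme; no exact placental match
NGE	triplet	unknown	unassigned	elephant shark granzyme A/K relative; specificity not assignable from the triplet
GNN	triplet	unknown	unassigned	fish-specific triplet; triplet-based prediction unreliable (phage display contradicts it)
GGN	triplet	unknown	unassigned	fish-specific triplet; triplet-based prediction unreliable
GTH	triplet	unknown	unassigned	fish-specific triplet; triplet-based prediction unreliable
GSS	triplet	unknown	unassigned	fish-specific triplet; triplet-based prediction unreliable
GAY	triplet	unknown	unassigned	fish-specific triplet; triplet-based prediction unreliable
GSY	triplet	unknown	unassigned	fish-specific triplet; triplet-based prediction unreliable
GTY	triplet	unknown	unassigned	fish-specific triplet; an enzyme with this triplet proved a specific tryptase
D	pos189	tryptase	putative	fallback on position 189 only; Asp favours basic P1
S	pos189	chymase	putative	fallback on position 189 only; Ser pocket pattern of chymases
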