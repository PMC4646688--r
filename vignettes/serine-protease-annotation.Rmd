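---
title: "Annotating hematopoietic serine proteases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating hematopoietic serine proteases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serprot)
```

## The problem

Granule serine proteases of mast cells, neutrophils, cytotoxic T cells and
NK cells form a large trypsin/chymotrypsin-fold family whose members are
compared through canonical chymotrypsinogen numbering: a residue is "189"
or "195" by its position in the fold, not in the raw sequence. Three
annotation questions recur in comparative work on this family:

1. Which residue of *this* sequence sits at canonical position X?
2. What primary cleavage specificity does the S1 pocket (positions 189,
   216, 226) suggest, and is the catalytic triad (His57, Asp102, Ser195)
   even intact?
3. Which genes constitute the orthologous locus in *this* genome, given
   that the protease genes themselves duplicate, die and invert while the
   non-protease genes flanking the locus stay put?

serprot answers these with a numbering module, a feature/classifier pair, a
synteny-based locus module, a distance-phylogenetics module, and a
simulator that generates data with known truth for validation.

## Canonical numbering by pairwise anchoring

Canonical numbering is classically carried through a large multiple
alignment. serprot instead aligns each query pairwise to a single bundled
**reference scaffold** whose residues carry the canonical labels. Because
the coordinate system is *defined* relative to chymotrypsinogen, a pairwise
anchor is faithful, and it makes the operation testable in isolation. The
bundled scaffold is synthetic: a fixed 245-residue chymotrypsinogen-like
sequence with the registry residues planted at their canonical positions
(His57, Asp102, Ser195; Ser189/Gly216/Gly226; Cys191/Cys220; a
non-cysteine at 93). No real database sequence is required, and tests build
their own scaffolds with `reference_scaffold()`.

The alignment is exact global Needleman–Wunsch with affine gaps, BLOSUM62
scoring, and a compiled dynamic-programming core:

* `gap_open = -11`, `gap_extend = -1` (the conventional pairing for
  BLOSUM62-class matrices); a gap of length $L$ costs
  $\mathrm{open} + (L-1)\,\mathrm{ext}$.
* `X` scores 0 against everything: unknown residues neither attract nor
  repel the alignment.
* Traceback ties break deterministically (diagonal > up > left, and
  match-state preference within each cell), so outputs are bit-identical
  across runs and platforms.

Numbering then reads the alignment column-wise: reference label L maps to
the query index aligned to it; labels in query deletions are absent; query
insertions get **no** label (no "95A"-style insertion codes — the numbering
consumers here never use them). `residue_at()` returns `NA` for absent
labels, which downstream code renders as `-`.

```{r numbering}
sc <- scaffold_default()
ns <- assign_numbering(align_global(sc$residues, sc))
residue_at(ns, 195)
extract_triplet(ns)
```

Correctness is checked against an independently written plain-R dynamic
program on hundreds of random instances, and by planting-and-recovery
through the simulator.

## Features and the specificity classifier

`specificity_profile()` reads five things off a numbered sequence: the S1
triplet (189/216/226), the triad residues and an **exact** H/D/S intactness
check (no conservative substitutions — triad loss is treated as a binary
inactivity call, the azurocidin pattern), the Cys93 dimerisation site, and
the presence of cysteines at both 191 and 220. Two caveats are deliberate:
the bridge flag is sequence-level only (two cysteines present, not a
structural disulfide assignment), and the monomer/dimer call is a
heuristic — it does not model alternative pairings of Cys93.

The classifier is a deterministic three-stage lookup:

1. **Inactive override.** A broken triad wins regardless of triplet: a
   non-enzyme's pocket residues carry no specificity information.
2. **Literal rules.** The packaged table maps known triplets to
   specificities: tryptase (DGG; DGA; GSD for the PRSS57/NSP-4 group),
   chymase (SGA; SGG and SGN as putative), asp-ase (SGR, TGR, AGR; SGK
   putative), cathepsin G-like chymase-with-tryptase (SGE, AGE), met-ase
   (ASP; AST), elastase (GVD, GID, NVA, NVS; SVN putative), and a set of
   triplets shipped explicitly as *unassigned* (NGE plus the fish-specific
   GNN, GGN, GTH, GSS, GAY, GSY, GTY). The fish triplets are hard-coded as
   unassigned rather than guessed because triplet-based prediction is known
   to fail for them — an enzyme with GTY proved to be a highly specific
   tryptase experimentally.
3. **Position-189 fallback.** If no literal rule fires, Asp189 suggests
   tryptase and Ser189 chymase, both tagged `putative`. This encodes the
   established informativeness hierarchy: 189 dominates, 226 is secondary
   (it can be shielded by neighbouring residues), 216 is least informative.

Duodenases — ruminant chymase-locus proteases with dual tryptic/chymotryptic
activity — get no rule: their triplets do not separate them, and shipping a
rule would overstate what the triplet can say. Whether SGK should outrank
the Ser-189 fallback is asserted in the literature only as "most likely";
it ships as asp-ase-putative. The table is a TSV config
(`specificity_rules(path=)`) so users can extend it; the packaged default
is the reference behaviour, and an enumeration test guarantees all 8,000
triplets produce a defined outcome under exact > putative > unassigned
precedence with the inactive override on top.

## Locus reconstruction and maps

Coordinates are 0-based half-open internally; GFF3 (1-based inclusive) is
converted on read and write, BED passes through. Structurally malformed
annotation lines are rejected and logged with line numbers rather than
aborting the read; records that are degenerate after normalisation are
likewise rejected and logged. Pseudogene flags are carried from annotation
attributes as display information only — the package never re-derives them
from sequence.

`identify_locus()` matches a definition's left/right marker genes
case-insensitively through an alias table (assembly-specific names such as
RNF17-for-STXBP6 in mouse), then takes the maximal run of genes between the
innermost matched left and right markers on one contig, absorbing
contiguous same-side markers immediately outside the pair. Several
candidate regions may match (paralogous loci); all are returned, ranked by
matched-marker count. When the two marker sides only resolve to different
contigs the locus is reported `split` with partial maps per contig — the
platypus-style situation. No matched marker yields an empty result with a
diagnostic, not an exception. The packaged definitions encode the chymase
locus (RIPK3/NYNRIN/CBLN3/SDR39U1 … STXBP6), the met-ase locus
(POLRMT … FSTL3 with FGF22/BSG/RNF126 central) and the fish chymase-related
locus (RABL3-like … CD276/ERCC1-like); the granzyme A/K locus ships with
empty marker lists because its flanking genes are conserved but not named
in the source text, so the user supplies them.

Geometry is plain arithmetic (size = end − start; intergenic distance =
next start − previous end, clamped to 0 with an overlap flag), with the
invariant that sizes plus gaps equal the locus span for non-overlapping
loci. Inversion detection compares each marker's strand with a
user-supplied reference orientation. Maps are rendered as deterministic
SVG: widths proportional to base pairs, protease genes at exactly twice
the height of other genes, strand as an arrowed glyph, fixed numeric
formatting so equal inputs give byte-identical documents. `autoplot()`
offers the same layout as a ggplot.

## Distance phylogenetics

The module re-implements the classical distance arm: column bootstrap →
distances → neighbor joining → majority-rule consensus.

* **Distances.** `p-distance` (mismatch fraction over comparable columns:
  both non-gap and non-X) and the Poisson correction $d=-\ln(1-p)$.
  The maximum-likelihood JTT distance is *not* re-implemented: the
  downstream conclusions rest on topology robustness, and the simpler
  corrections keep closed-form expectations available for testing. The
  model name travels in the output metadata. Saturated pairs ($p \ge
  0.95$, configurable) are capped at the cap's distance with a warning.
  Non-negativity and symmetry always hold; the triangle inequality is not
  asserted (the Poisson correction can violate it).
* **NJ.** Standard Q-criterion joins with the usual branch-length
  formulas; lowest-index tie-breaks make runs bit-reproducible; negative
  branch lengths are clamped to 0 with a warning (the PHYLIP-compatible
  choice). On additive matrices the generating topology is recovered with
  exact lengths.
* **Bootstrap.** Default 100 replicates (the standard protocol for this
  analysis). One master seed drives per-replicate substreams, so replicate
  $i$ is independent of how many replicates run; supports are integer
  percentages of replicates containing each internal bipartition of the
  full-data tree, attached as node labels. `tidy()` returns the
  bipartition/support table, `glance()` the one-row summary.
* **Consensus.** Exactly the bipartitions with frequency strictly greater
  than the threshold (default 0.5); no greedy completion of compatible
  minority splits.
* **Newick.** A small recursive-descent reader/writer is included because
  the round-trip contract covers quoted labels containing spaces and parse
  errors that report character offsets; it is fuzz-tested against its own
  writer and cross-checked against ape on plain trees.

A least-squares comparison is out of scope: for the figures this package
serves, it is redundant with NJ, and only NJ is implemented. Bayesian MCMC
and maximum-likelihood inference are likewise out of scope; alignments are
expected from upstream tools.

## The simulator

`simulate_family()` emulates the statistical structure the protein-level
pipeline assumes: a root drawn from the scaffold with a chosen planted
triplet/triad/cysteine layout, evolved along a (given or sampled) tree
under a uniform 20-state Jukes–Cantor-like model — per branch and site the
substitution count is Poisson(rate × length), each event replacing the
residue with one of the other 19 uniformly. This model was chosen over an
empirical matrix precisely because it has a closed form,
$P(\text{same}) = \tfrac{1}{20} + \tfrac{19}{20}
 e^{-\frac{20}{19} r t}$ (`expected_identity()`), against which simulated
divergences are tested; the substitution model is an internal seam that
could be swapped. Canonical registry sites are frozen by default so planted
features survive arbitrary divergence, and indels (off by default) are
never placed within 3 residues of a frozen site, keeping planted-site
recovery exact — realistic indel placement is a non-goal. Every run records
an event log that replays to the emitted sequences byte-for-byte, which is
itself tested.

`simulate_locus()` lays out marker–protease–marker contigs with realistic
scales (protease genes 2–6 kb, markers 5–40 kb, intergenic gaps 1–50 kb)
and applies duplication, loss, inversion and split events, either at
Poisson rates or forced, with a replayable event record. Defaults are
deliberately quiet (all event rates 0) so each test or example turns on
exactly the dynamics it studies.

One master seed drives named substreams (tree, sequences, locus layout),
so adding draws in one stream never perturbs another — fixtures stay
byte-stable across package growth. `make_fixture_suite()` packages a
deterministic set covering every literal classifier rule, a broken-triad
sequence, a 6-taxon family on a long-internal-branch tree, and loci with a
forced inversion and a forced split, with a JSON manifest of all planted
truths.

What passing these tests does *not* show: real proteases diverge under
site-heterogeneous, matrix-structured substitution with indels near
functional sites, real annotations contain fragmented assemblies and
misnamed genes, and real loci rearrange by mechanisms richer than the four
event types modelled. The simulator validates the machinery, not the
biology.

## Numerical and testing choices

* Alignment, NJ and consensus tie-breaks are all lowest-index/deterministic;
  repeated runs are bit-identical.
* The alignment oracle in the test suite is an independently written plain-R
  dynamic program; the NJ oracle is exhaustive topology enumeration with
  least-squares fitting for up to 6 leaves (3/15/105 topologies), while
  7–8-leaf trials use the equivalence that on an additive matrix the unique
  generating tree is identified by reproducing the input distances exactly,
  plus agreement with the known generating topology. Problem sizes
  (200 random alignments up to 60 residues; 100 NJ trials at 4–8 leaves;
  a 10-taxon, 200-column bootstrap) keep the whole suite under a minute of
  phylogenetics work while exercising every code path.
* Classifier exhaustiveness is checked by full enumeration (8,000
  triplets), not sampling.

## Known limitations

* Numbering is pairwise-anchored; deeply divergent sequences that would
  benefit from profile information may misalign locally. No insertion
  codes are produced.
* The oligomer call and bridge flag are sequence-level heuristics.
* Specificity prediction is only as good as the triplet rules; the package
  itself ships several triplets as explicitly unassigned because
  experimental evidence contradicts naive reading of the pocket.
* Distances are p/Poisson only; for publication-grade trees users will
  want to corroborate topologies with likelihood or Bayesian tools.
* Locus identification requires user-supplied (or packaged) marker
  definitions; it does not infer synteny de novo and does not search for
  homologs — annotations come from upstream.
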