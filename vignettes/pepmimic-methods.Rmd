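---
title: "Designing peptides that mimic discontinuous epitopes: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing peptides that mimic discontinuous epitopes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmimic)
```

## The problem

A discontinuous (conformational) B-cell epitope is a set of residues that
an antibody contacts on the folded antigen surface; in sequence space those
residues are scattered over several short stretches. Synthesising a linear
peptide that can stand in for such an epitope requires deciding (i) which
surface residues to take and (ii) in which order to concatenate them.
`pepmimic` treats this as a family of path problems over the antigen
surface and provides 34 deterministic design methods plus the evaluation
machinery to compare their output with crystallographically observed
epitopes.

## Surface model

Everything starts from per-residue solvent accessibility. We compute
Shrake–Rupley SASA with a deterministic Fibonacci sphere (960 points per
atom by default, probe 1.4 Å, Bondi-type element radii), normalise by the
residue's theoretical maximum in an extended Gly-X-Gly context, and call a
residue *accessible* when its relative SASA reaches a threshold.

* **Threshold (default 0.05).** Published descriptions of this design
  approach do not state the accessibility criterion. We default to a
  permissive 5% relative SASA because epitope surveys consistently find
  that only a small minority (~12%) of epitopic residues are buried; a
  stricter threshold would amputate real epitopes from the surface model.
  Both the threshold and the probe radius are arguments of
  `compute_accessibility()`.
* **Segments** are maximal runs of accessible residues that are contiguous
  in the chain: consecutive in the residue ordering *and* either stepping
  the residue number by one or continuing an insertion-code series. A
  numbering gap is treated as a chain break — this matters for real PDB
  files with unmodelled loops.
* **Clusters** group segments by average-linkage hierarchical clustering on
  centre-of-gravity distances, cut at a height of 20 Å. The historical
  tool delegated this step to a clock-constrained least-squares phylogeny
  program; that exact procedure (and its tree-cutting rule) is not
  recoverable, so we ship a deterministic functional stand-in that
  reproduces the qualitative behaviour — the number of clusters grows only
  weakly with antigen size. The cutoff is a parameter of
  `build_clusters()`.
* **Patches** come in two flavours. Fixed-radius patches collect all
  segments whose centre of gravity lies within 10 or 15 Å (inclusive — the
  same convention as the 4 Å epitope contact cutoff) of a reference
  segment's centre of gravity; there are exactly as many patches as
  segments. Varying patches are residue-level: for each accessible residue
  we count accessible residues within 15, 16, …, 20 Å of its CA and keep
  the smallest radius whose count reaches the mean of the six counts. When
  no count equals the mean exactly, "reaches" (first count ≥ mean) is our
  reading of collecting the average number. Membership counts accessible
  residues only, because peptides are built exclusively from accessible
  residues.
* **Centre of gravity** is the unweighted mean over a segment's heavy
  atoms; no mass weighting is implied anywhere in the method definitions.

## Design methods

**Prime methods.** `NN` grows a peptide C-terminally from a reference
segment, each time appending the unused segment nearest to the most
recently added one (chained growth: the candidate ranking follows the
forming end of the peptide, not the fixed reference; this is configurable
in spirit but chained is the default because it is the only reading in
which a "forming peptide" has a growth front). `uNN` additionally chooses
each segment's sense: if the segment's C-terminal CA is closer to the
peptide's current C-terminus than its N-terminal CA, the segment is
appended reversed; ties keep natural sense. `FN` appends alternately C-
and N-terminally so the reference stays central. Growth stops when the
requested length is reached; an overshooting segment is added whole, which
is why final lengths systematically exceed requested lengths by a couple
of residues. `ONN`/`OFN` re-order the NN/FN segment set, and `OPP` the
members of the reference's 10 Å patch, to minimise the total
centre-of-gravity distance of the arrangement; no extra residue is added.
Within the optimisers we keep every segment in natural sense — reversal is
a uNN-specific device and nothing in the method definitions licenses it
elsewhere.

**Linker methods.** `*ala` inserts `max(0, round(gap/3.8) − 1)` alanines
at each junction, where the gap is the distance between the C atom of the
preceding junction residue and the N atom of the following one and 3.8 Å
is the span of one virtual peptide bond: zero insertions when one bond
already spans the gap, one more alanine per additional bond the distance
allows. `*sa` encodes both segments in the 16-letter protein-blocks (PB)
structural alphabet and consults the PB transition table: an allowed
junction transition inserts nothing; otherwise the one or two blocks with
the best bottleneck transition weight are inserted, realised as each
block's preferred amino acid at the central window position, and a
junction with no 1- or 2-block bridge marks the peptide "not possible"
(such peptides are excluded from banks). `*sas` always inserts exactly one
residue: the junction's 5-residue window (last two residues of the
preceding segment, first three of the following, dihedrals computed across
the spatial gap) is assigned to the closest PB prototype by angular RMSD,
and that block's preferred central amino acid is inserted.

**Graph methods.** Three graphs are built with Euclidean edge weights: a
directed segment graph (C-terminus of *i* to N-terminus of *j*; paths
traverse segments N→C only), its undirected counterpart (minimum over the
four terminus pairings) and an undirected accessible-residue graph (CA–CA).
`SHP*` returns, over all pairs of area members, the shortest path covering
the most residues. On a *complete* Euclidean graph the direct edge is
always a shortest path, which would degenerate every SHP peptide to two
elements; shortest-path methods therefore operate on neighbour graphs with
a connection cutoff (defaults: 8 Å for the residue graph, 20 Å for segment
graphs — roughly two peptide bonds and one segment-hop respectively).
`TSP*` solves the open travelling-salesman path over the area (exact
dynamic programming to 12 nodes, nearest-neighbour + 2-opt beyond, a
conventional exactness boundary that keeps worst-case areas tractable),
slides along the optimal path enumerating every run that first reaches the
requested length, and selects the final run by variant: highest segment
score (1), shortest travelled distance (2), shortest distance per segment
(3), containing the area's two closest members (4); the residue-level
`TSPaa` uses the shortest distance. For variant 1 the score is computed on
the candidate run only — scoring the whole path would make all runs tie.
Segment-graph methods design one peptide per cluster and per 15 Å patch;
residue-graph methods one per cluster and per varying patch.

All tie-breaks anywhere in the engine (equal distances, equal scores,
equal coverage) resolve lexicographically on element identifiers, which
makes every bank byte-reproducible without any seed.

## Scoring

`Sp = Σ Ss` over the peptide's segments, with
`Ss = Naa + Naccess + Nhyd + Nwryp + Nturn`: residue count, mean relative
SASA of the segment × 10, hydrophobic count over {A, C, F, I, L, M, V, W},
W/R/Y/P count (a tryptophan increments both terms — the score's components
are defined independently and nothing suggests exclusivity), and the
number of residues inside hydrogen-bonded turns. Turns are assigned from
the structure with a DSSP-style criterion: amide hydrogens rebuilt from
the preceding carbonyl, Kabsch–Sander electrostatic energy below −0.5
kcal/mol between CO(i) and NH(i+3..5), residues strictly between the
bonded pair flagged. The ×10 scaling of `Naccess` makes the accessibility
term commensurate with the counting terms and is the scoring formula's
largest unknown; it is exposed as an argument in spirit (the term can be
disabled by zeroing `sasa_rel`) and stated here so users can judge score
comparisons accordingly.

## Evaluation

The crystallographic epitope of a complex is every antigen residue with a
heavy atom within 4 Å (inclusive) of any antibody atom; hydrogens are
absent from typical X-ray models and are ignored throughout. Composition
Se/PPV uses multiset matching — each epitope residue can credit at most
one peptide position — which is the counting reading of the usual
alignment pictures; nothing in the definitions suggests set semantics.
Position-aware Se/PPV credits a peptide position only when its source
residue is an (un-credited) epitope residue; linker positions, having no
source, are compared last by identity. Thresholded summaries use strict
inequalities on both metrics simultaneously ("higher than 0.7").
Multiple epitopes per antigen are scored independently; summaries treat
each complex as one epitope.

The chance baseline has two parts: `random_baseline()` draws peptides
i.i.d. from the antigen composition with lengths from the empirical
designed-length distribution (single seed argument, no global RNG state),
and `chance_probability()` gives the closed-form probability of a specific
sequence as an ordered draw without replacement from the accessible
residues, computed in log space so 20-residue peptides on large antigens
do not underflow.

## Protein-block data

The 16 PB prototype dihedrals bundled under `inst/extdata/pb/` are the
published reference angles of the protein-blocks structural alphabet
(de Brevern, Etchebest & Hazout 2000). The transition weights and
per-position amino-acid propensities of the PB literature are *not*
redistributed here; the package ships clearly labelled synthetic
stand-ins: transitions derived from the geometric compatibility of the six
dihedrals shared by overlapping 5-residue windows (weight
`exp(−RMSDA/30)`, zero beyond 80°), and propensities formed by weighting
Chou–Fasman helix/sheet/turn propensities by each window position's fuzzy
backbone-basin membership. Both files are deterministic outputs of
`data-raw/make_pb_data.R`, carry their derivation in their headers, and
are interchangeable with externally supplied tables — every PB operation
accepts the table as an argument. Consequences for interpretation: PB
*encoding* (helix → `m`, extended → `d`, and so on) matches the published
alphabet, while the specific linker amino acids chosen by the SA/SAS
methods reflect the synthetic tables and would differ with the original
statistics.

## The synthetic benchmark

`make_structure()` builds ideal-geometry backbones (N, CA, C, O, CB) from
per-residue dihedral templates; `make_complex()` plants antibody contacts
as single-glycine probe residues placed so the minimum heavy-atom distance
to the target residue equals the requested value to better than 0.01 Å
(the approach direction is searched for maximal clearance from other
residues, and probes carry non-consecutive residue numbers so no peptide
bond is implied between them). `make_benchmark_complex()` draws antigens
of 30–50 residues with mixed secondary structure, a mostly-accessible
surface with a few buried stretches, and epitopes of 2–5 segments of 1–4
residues — mirroring the published statistics of crystallographic
discontinuous epitopes (a handful of segments averaging ~2.4 residues).

What the generator does **not** emulate: real side chains (fixtures are
poly-Ala-like with a CB stub; SASA is therefore backbone-dominated), real
antibody paratopes (probes are single glycines), crystallographic noise,
and antigens at full protein size (benchmark antigens are an order of
magnitude smaller than typical dataset antigens). Passing tests therefore
demonstrate the correctness of the algorithms and their invariants, not
field performance on real antigens; headline benchmark statistics from the
literature (mean Se ≈ 0.34–0.49, mean PPV ≈ 0.39–0.57 over 75 complexes)
require the external crystal dataset and are documented pipeline outputs
rather than test expectations. It is reassuring, though not evidential,
that on the synthetic benchmark the fraction of peptides clearing the
0.7/0.7 bar lands in the same few-percent regime reported at full scale.

## Numerical choices and degenerate inputs

* Distances, cutoffs and coordinates are in Å throughout; boundary
  conventions are inclusive (≤) everywhere.
* Residues without atoms are flagged inaccessible with a warning, never an
  error; structures with no accessible residue yield an empty segment
  table with a warning.
* A disconnected SHP area degrades to a single-element peptide; an area
  smaller than the requested TSP length returns the whole path flagged
  `"short"`.
* Relative SASA is clamped at 1 (an isolated residue can exceed its
  Gly-X-Gly reference).
* `round()` in the alanine rule is R's banker's rounding; gaps landing
  exactly halfway between bond counts are vanishingly rare in real
  geometry.
* Problem sizes in the test-suite and acceptance script (six 30–50-residue
  antigens, 100 optimizer trials at ≤ 8 elements, 1000 evaluation pairs)
  were chosen as the smallest sets that exercise every method family and
  keep the brute-force oracles exhaustive.

## Known limitations

The cluster construction is a stand-in, not a port, of the original
phylogeny-based grouping; absolute cluster compositions will differ even
though counting rules and downstream behaviour are preserved. The SA/SAS
linker identities depend on synthetic PB statistics (see above). The
score's `Naccess` scaling is a declared convention. And the package
deliberately omits the continuous-epitope method, paired-peptide design
and any web front-end: its scope is the discontinuous-epitope design
engine and its benchmark.
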