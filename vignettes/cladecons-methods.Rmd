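---
title: "Clade-aware conservation profiling: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-aware conservation profiling: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladecons)
```

## The analysis in one paragraph

`cladecons` studies how a gene family diverges after duplication by
measuring, clade by clade, the conservation of every alignment column.
Its motivating system is the plant D14/KAI2 α/β-hydrolase family, where
one super-clade (eu-KAI2, the karrikin/KL receptor lineage) is highly
conserved across all land plants while its sister super-clade (DDK,
containing the strigolactone receptor D14) is divergent and
heterogeneous. Three complementary statistics capture this: cumulative
conservation tiers per position, clade-characteristic residue sets that
diagnose clade identity of individual sequences, and conservation of
named functional residue sets such as the MAX2 F-box interaction
interface. All three operate on a *core alignment* with a unified
residue numbering.

## Core positions and unified numbering

Family alignments that include transcriptome-derived entries are ragged:
sequences start and end at different points, and a few sequences carry
insertions. The package replaces manual trimming with one tunable rule:
a column is a **core position** when its non-gap occupancy is at least
`occupancy_threshold`.

* `occupancy_threshold` (fraction, default **0.90**): at 0.90 a column
  survives when nine in ten sequences have a residue there, which
  tolerates a realistic load of truncated fragments while discarding
  ragged termini and private insertions. The achieved number of core
  positions is always reported, never assumed; on a curated family
  alignment the threshold can be calibrated until the published core
  size is reproduced.
* An `X` (unknown residue) counts as *occupied* for the occupancy rule —
  a fragment is physically present there — but is excluded from all
  frequency denominators downstream, because it carries no residue
  information.

Non-core columns between the first and last core column become
**insertions**, catalogued per sequence and keyed to the nearest
preceding core position ("after position *k*", with 0 meaning before
the core starts). Non-core columns outside that span become terminal
extensions. This decomposition is lossless at the residue level: for
every sequence, N-extension + core residues + catalogued insertions +
C-extension equals the original sequence with its alignment gaps
removed. Gap placement *within* discarded low-occupancy columns is an
arbitrary choice of the aligner and is deliberately not retained.

Residue numbers of a reference sequence (for the D14/KAI2 family,
Arabidopsis KAI2, whose numbering is +1 relative to the unified scheme)
map onto unified positions either through a fixed offset or, when the
anchor is gapped or carries insertions, by walking its residues across
the core (`set_anchor()`, `map_position()`). The walk refuses to map a
residue that falls inside an extension or insertion rather than
silently returning a neighbouring column.

## Conservation tiers

For a subset *S* of sequences, position *p* has modal residue and
fraction computed over **observed** residues only (non-gap, non-X).
Tiers are cumulative, with **strict** lower bounds:

| tier | bound |
|---|---|
| conserved | f > 0.50 |
| well conserved | f > 0.70 |
| highly conserved | f > 0.90 |
| invariant | f > 0.99 |

Strictness matters at the edges: 96/100 is *highly conserved*, not
invariant, and exactly 50% is not conserved. Two residues tied at the
top are resolved alphabetically and flagged (`tie = TRUE`); a tie at
exactly 50% can therefore never count as conserved. Positions with no
observed residue in the subset are classified `unobserved` and excluded
from tier numerators while the denominator stays the full core length.

Excluding gaps and X from denominators is a deliberate design choice:
with fragmentary sequences in the subset, an all-sequences denominator
caps attainable "invariance" far below 100% for reasons that have
nothing to do with evolution. The all-sequences denominator remains
available (`include_gaps = TRUE`) for sensitivity analysis.

Summary percentages are rounded half **away from zero** to one decimal
(the convention of printed tables; R's `round()` would round half to
even), and unrounded values are kept alongside in every report.

## Characteristic residue sets and match scores

A (position, amino acid) pair is characteristic of a focal group
against one or more contrast groups when

* `freq(a | focal) >= in_min` (default **0.70**), and
* `freq(a | contrast) < out_max` (default **0.30**) for every contrast
  group independently.

The published analyses this design follows phrase the focal bound
inconsistently ("at least 70%" in one search, "more than 70%" in
another); the package applies one uniform rule (`>=` / `<`) with both
bounds configurable. With defaults, at most one amino acid per position
can qualify; if looser bounds ever admit several, the highest focal
frequency wins (alphabetical on ties) so that positions stay unique.
Raising `in_min` or lowering `out_max` can only shrink the set, and a
search with focal and contrast exchanged can never share an entry with
the forward search while `in_min >= out_max` — both properties are
enforced by tests.

Match scores report three integers per sequence — `matched`,
`observed`, `total` — rather than a single percentage, because a
truncated sequence that matches 10/10 observed positions of a 39-entry
set is not evidence of clade membership comparable to 38/39. Sequences
with `observed/total < 0.8` are flagged `fragmentary` and excluded from
per-clade min–max ranges by default.

## Residue-set (interface) assessment

For a named residue set, "conserved in clade *C*" defaults to the
conjunction: the clade's modal fraction strictly exceeds the conserved
bound (0.50) **and** the modal residue equals the reference residue.
The two sub-criteria are reported separately per position
(`meets_frequency`, `matches_reference`) so that alternative
definitions can be audited without recomputation; the frequency bound
is also adjustable (`conserved_bound`). Clades may be pooled
(`list(monilophyteDDK = c("DDKA", "DDKB"))`) when the biological
question concerns a union of sister clades; both pooled and separate
modes are available because published counts of this kind do not always
state which was used. `compare_clades()` ranks clades by the number of
failing positions, descending, ties alphabetical.

## Dataset variants

`apply_variant()` and `jackknife_series()` produce the pruned and
clade-deletion datasets used to test tree-topology robustness. Masked
"positions" are counted in **amino acids on the untrimmed alignment**
and expanded to nucleotide triples on codon alignments (5 positions =
15 nucleotides); the manifest records the scale explicitly, together
with exact sequence and column removals, because position lists quoted
in methods sections are ambiguous about their coordinate system. Tree
inference itself is out of scope: the module emits alignments plus
manifests for external ML software.

## The synthetic generator

`generate_family()` emulates the structure of a real family alignment
so that every analysis can be validated against known truth:

* **Clade structure.** Each clade has a consensus sequence; clades share
  consensus except at planted diagnostic columns.
* **Tiers.** Each column carries a planted tier. The number of
  sequences deviating from consensus in a clade-column is drawn
  `Binomial(n, 1 - m)` where *m* is the midpoint of the tier's band
  (0.995 / 0.945 / 0.80 / 0.60 / 0.25), then clamped into the band, so
  the realized within-clade modal fraction always lies inside the
  planted tier. This makes tier recovery well-posed: recovered
  percentages equal planted ones by construction, and the test
  tolerance (2 points at n = 200/clade) covers only boundary effects.
  At very small *n* some bands collapse (a "highly conserved" column
  cannot be realized in 4 sequences); the clamp then picks the nearest
  feasible count.
* **Diagnostic columns.** The designated focal clade gets a distinct
  consensus residue; deviant draws at these columns exclude both pair
  residues, so cross-clade leakage of the focal residue is exactly
  zero. Diagnostic columns are planted in the central 30–70% span of
  the core so a clade signal is never confounded with terminal missing
  data.
* **Insertions.** Random singleton insertions (Poisson per sequence,
  lengths 1–5) plus optional clade-conserved insertions (same site,
  same shared segment, in a chosen fraction of a clade) appear as extra
  low-occupancy columns.
* **Fragmentation.** A chosen fraction of sequences (default 0.30,
  mimicking transcriptome-derived entries) is truncated at one terminus
  by a uniform 5–25% of the alignment length — contiguous terminal
  stretches only, never internal windows.
* **Determinism.** One integer seed governs everything; identical spec
  and seed give byte-identical output, and the generator restores the
  caller's RNG state.

What the generator does **not** emulate: phylogenetic correlation
(columns are independent; there is no evolution along a tree), among
clade consensus divergence at non-diagnostic positions, indel alignment
ambiguity, and sequencing error beyond the uniform deviation model.
Passing the synthetic-recovery tests therefore demonstrates the
correctness of the counting, classification and bookkeeping — not
robustness to alignment error or phylogenetic non-independence, which
must be judged on real data.

The default tier mixture (6.8 / 10.9 / 24.9 / 25.7 / 31.7% for
invariant / highly / well / conserved / variable) reproduces the
family-wide cumulative profile of the motivating dataset, so a
defaults-only simulation "feels like" a D14/KAI2-sized problem.

## Problem sizes and numerical choices

* Property tests run on exhaustive small alignments (up to ~10 × 20,
  dozens of random instances against brute-force counting oracles);
  recovery tests use two clades of 200 sequences over a 265-position
  core — the scale of the motivating study — and complete in seconds.
* Back-translation draws synonymous codons uniformly under the standard
  genetic code; gaps map to `---` and `X` to `NNN`, making
  `translate_codons()` an exact left inverse. Translation renders any
  codon containing `N` or a partial gap as `X`; in-frame stops are kept
  as `X` with a warning rather than failing, since deposited family
  alignments occasionally contain mis-called ORF boundaries.
* All report files are written as TSV plus a JSON mirror with unrounded
  values; re-reading a report yields identical values. Pipeline runs
  are deterministic given configuration and inputs, and each stage
  writes a manifest (package version, parameters, input checksums).

## Known limitations

* The occupancy threshold is a proxy for manual curation; on a real
  alignment the achieved core size should be inspected (and the
  threshold calibrated) before unified positions are quoted.
* No phylogeny-aware weighting: every sequence counts once, so clades
  with dense paralogue sampling from single species weigh more.
* No statistical significance testing of characteristic residues; the
  in/out bounds are descriptive thresholds, not hypothesis tests.
* Modal-fraction conservation ignores biochemical similarity
  (no substitution-matrix or entropy scores).
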