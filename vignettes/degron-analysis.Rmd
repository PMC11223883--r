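---
title: "Degron discovery, proteolysis and terminal stability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degron discovery, proteolysis and terminal stability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degronkit)
```

degronkit analyses protein degradation signals along three axes: where
degron motifs sit in a sequence, whether their structural context makes
them plausible (the tripartite model), and how stable a protein's termini
are predicted to be — including termini that only exist after proteolytic
cleavage. This vignette explains the models and the choices behind them;
everything stated here is computed by the package's functions and checked
by its test suite.

## Queries and coordinates

Queries are protein tibbles from `read_fasta()` or structure models from
`read_structure()` (single model, single chain, residue numbering
continuous from 1, file at most 5 MB, B-factor column interpreted as
pLDDT/LDDT for predicted models). Validation (`validate_query()`) collects
*all* failures rather than stopping at the first: sequences must be
non-empty, strictly shorter than 40 000 residues and limited to the 20
canonical residues. The placeholder X can be admitted with `allow_x =
TRUE`, but X never satisfies a motif character class — rejecting
non-canonical letters by default is the conservative reading of a
canonical-residue contract, and a permissive `allow_x` covers real UniProt
entries with placeholders.

Methionine aminopeptidase removes many initiator methionines in vivo, so
`met_variants()` expands each Met-initiated protein into as-given and
Met-cleaved forms and the scanner screens both. All coordinates are 1-based
and reported in the full-length (as-given) frame; matches from the cleaved
variant carry `met_variant = "met_cleaved"` and an implicit +1 shift, so an
N-terminal match on that variant always surfaces at full-length position 2.
A single-residue "M" protein yields only the as-given form, since the
cleaved form would be empty.

## The motif dialect

Degron motifs are short linear motifs, so the pattern language is a
deliberately restricted regex subset: residue literals, the `x` wildcard,
positive and negated classes, and bounded repeats. No anchors (location
semantics live in the motif's `location_class`, so one motif row serves
both Met variants), no alternation, no lookaround, no unbounded
quantifiers. The restriction keeps every match enumerable, which in turn
makes the brute-force oracle in the tests trivial: the matcher must
reproduce, exactly, the result of testing the pattern at every start
position and every admissible length. Overlapping and nested matches are
all reported — downstream tripartite analysis is per-match, and greedy
suppression would silently drop context.

The packaged starter set (`builtin_motifs()`) covers the Arg/N N-terminal
residue classes, six representative C-degron motifs and three internal
motifs, each with a literature citation in its `source` field. It is a
working default, not a compendium; curated tables load through
`load_motifs()` with the same schema.

## Structural context and disorder

Solvent accessibility is normalized as RSA = ASA / MaxASA with the Rost &
Sander (1994) residue maxima, clamped at 1 (predicted or low-resolution
structures occasionally exceed the tabulated maxima). Secondary structure
and ASA come from an external adapter function — typically wrapping a DSSP
binary — because hydrogen-bond assignment is a solved problem that should
not be re-implemented; with no adapter configured the pipeline degrades to
unknown secondary structure rather than failing, since motif-level results
do not depend on it.

Disorder has two modes with opposite threshold directions, matching how the
two score types are oriented:

* **structure mode** — the score is the residue pLDDT from the B-factor
  column; disordered means score `< 70`. A warning flags all-zero B-factor
  columns, which usually means the file is an experimental structure, not a
  predicted model. pLDDT is an imperfect disorder proxy (low-confidence
  regions are not always disordered), which is exactly why the threshold is
  exposed.
* **sequence mode** — disordered means score `> 0.5`. Any per-residue
  predictor can be plugged in as `predictor = function(sequence) ...`; the
  built-in fallback is the package's own windowed heuristic in the
  FoldIndex tradition: over a 21-residue window it contrasts mean
  Kyte–Doolittle hydropathy (rescaled to [0, 1]) with mean net charge,
  `FI = 2.785 * H - |Q| - 1.151`, mapped through a logistic so that
  `FI < 0` (disorder-favouring) gives a score above 0.5. It captures the
  charged/low-hydropathy signature of IDRs but not context-specific
  interactions; outputs label it as the built-in heuristic.

IDRs are maximal runs of disordered residues with length at least
`idr_min_len` (default 10 — about the shortest segment commonly called an
IDR rather than a flexible linker; configurable).

## Tripartite assembly

For each primary match, every K, C, S and T in the window
`[start − flank, end + flank]` (default flank 15) is reported as a
candidate secondary degron — lysine is the canonical ubiquitin acceptor,
and cysteine/serine/threonine cover non-lysine ubiquitination. Sites inside
the motif itself are included and flagged `within_primary = TRUE`, so the
caller can filter either way. Each site carries RSA, secondary structure,
IDR membership and the mean disorder over a ±5-residue site window
(`site_window`). The tertiary assignment reports the IDR minimizing
residue-interval distance (0 inside; otherwise distance to the nearer
boundary), with exact ties broken toward the N-terminal IDR — an arbitrary
but fixed rule that keeps results deterministic.

PTM and mutation overlays are pure decoration: PTMs attach anywhere in
motif ∪ flanks; missense mutations attach inside the motif and additionally
at PTM-bearing flank positions (a mutation that removes a flanking
phosphosite can rewire degron control). Overlay never alters upstream
positions or scores, and out-of-range annotation rows are rejected with the
row numbers named.

## Proteolysis

A cleavage event at position p cuts the bond p|p+1, so "cleavage at
position 77" produces fragments 1–77 and 78–L — the convention that makes
residue 78 the neo-N-terminus. Full digestion cuts all bonds at once and
must partition the parent exactly (a fuzz-tested invariant); single-site
mode treats each event independently, which is the right model for a
one-off maturation cut. Missed-cleavage enumeration is out of scope for
this version.

The 35 built-in enzyme rules use PeptideCutter-compatible semantics: one or
more site patterns over the subsite window P4–P3–P2–P1 | P1′–P2′, with
exception patterns that veto a cut (trypsin's classical exception table,
for example, is carried as vetoes on the trypsin rule). Positions beyond
the termini are padded with a neutral symbol that satisfies wildcards and
negated classes — the forbidden residue is certainly absent — but never a
positive requirement; this makes boundary behaviour explicit instead of
implementation-defined. Neo-termini of fragments are then re-screened:
N-terminal motifs and the N-end-rule class only at a *neo* N-terminus,
C-terminal motifs only at a *neo* C-terminus (the parent's original termini
were already screened on the parent), with positions reported in both
fragment and parent coordinates. Fragments are screened as-is, without
initiator-Met maturation, because a cut product's first residue is not an
initiator.

## Conservation scores

Given a user MSA containing the query row, matches map to alignment columns
through the gap-aware `col_map`. Four scores per match, all in [0, 1],
versioned in the output metadata (`degronkit-conservation-1`):

* **s1, anchored presence** — fraction of non-query rows where the motif
  matches exactly at the aligned span;
* **s2, windowed presence** — the same with the span widened by `flank`
  columns (default 5); s2 ≥ s1 by construction, and the gap between them
  separates strict positional conservation from motif drift;
* **s3, column identity** — mean fraction of rows matching the query
  residue per motif column;
* **s4, column conservation** — 1 minus the mean gap-excluded normalized
  Shannon entropy of the motif columns. s4 describes the columns
  irrespective of the query residue, so (unlike s1–s3) it is not monotone
  under adding query-identical rows; it answers "how variable are these
  positions", not "is the query's motif present".

Gaps never satisfy a motif token, rows that are entirely gaps across the
motif span are excluded from denominators, and a query-only alignment
yields NA scores rather than misleading zeros.

## PSI stability modelling

The Protein Stability Index of a terminal 23-mer is regressed from
sequence-derived physicochemical descriptors: amino-acid composition,
Gravy, net charge at pH 7 (Henderson–Hasselbalch with the EMBOSS pKa set),
average molecular weight, aromaticity, isoelectric point (bisection on the
charge curve) and aliphatic index — computed over the whole peptide and
over the terminal 10, 8, 6, 4 and 2 residues, with short peptides using the
available residues and recording the effective length as a feature. For
N-terminal peptides with a retained initiator Met, the windowed descriptors
skip the Met, so retained/cleaved models see comparable windows.
Cheminformatics descriptor blocks are intentionally omitted from the core
schema to keep the dependency footprint sequence-only.

The regressor is gradient-boosted trees (xgboost; 300 rounds, depth 5,
eta 0.1, fixed seed 42) behind a backend-agnostic interface — modest
defaults chosen for desk-scale reproducibility; no hyperparameter search is
performed or needed for correctness. Data split 90:10 train/test;
performance (R², RMSE) is reported on the held-out split and by 5-fold
random-permutation CV (20% validation per fold) on the training set.
Constant-target data short-circuit to a constant model instead of letting
the booster chase numerical noise.

Predictions map to five stability categories — most_unstable, unstable,
medium, stable, most_stable — using the 20/40/60/80th percentiles of the
*training* PSI distribution. Bins are right-closed (a value exactly at a
cut falls in the lower bin, so a PSI exactly at the 80th percentile is
"stable"); degenerate all-equal cuts yield "medium" with a warning. Lower
PSI always means less stable.

No trained weights ship with the package: real stability tables are
supplied by the user through `load_gps_table()` (schema: `protein_id`,
`terminus`, `peptide`, `psi`) and models are trained locally. The quantile
cuts and category labels are this package's documented choice.

## The synthetic data generators

`synthesize_proteins()` draws uniform-random canonical sequences — adequate
for property testing of scanning, digestion and windowing, which are
composition-agnostic. `synthesize_psi_dataset()` draws random 23-mers and
plants a known signal, by default `psi = 2 × Gravy(full) + N(0, σ)` with
σ = 0.1: hydrophobicity is a real correlate of terminal instability, and a
planted linear signal makes training a parameter-recovery exercise with the
generating function as oracle (held-out R² ≥ 0.9 at n = 5000 is asserted in
the tests at exactly those conditions). What these generators deliberately
do not emulate: realistic residue composition, homology structure within a
dataset, or the heavy-tailed, assay-specific noise of real stability
screens — so passing tests demonstrate algorithmic correctness, not
real-data predictive performance, which depends entirely on the training
tables supplied.

`synthetic_sde2_precursor()` is the worked-example fixture: a ubiquitin
UBL core closed by a diglycine at 76–77 with a lysine at 78 and a designed
(glycine-free) C-domain. It is labelled synthetic throughout; only the UBL
core is a natural sequence.

## Problem sizes and determinism

The test suite and the acceptance script run randomized property checks at
deliberate scales — 200 scanner instances against the brute-force oracle,
500 fuzzed digests, dozens of conservation and tripartite enumerations, and
one n = 5000 PSI recovery — all seeded, all completing in a few minutes on
one core. `run_pipeline()` is deterministic for fixed inputs and
configuration (report metadata carries no timestamps for exactly this
reason), and export/re-import of a TSV bundle preserves every table.

## Known limitations

* Structural (non-linear) degrons are out of scope; motifs are linear.
* The built-in sequence-disorder heuristic is a coarse stand-in for a
  dedicated predictor; use the adapter hook where one is available.
* Protease rules are specificity rules, not kinetics; no cleavage
  efficiency is modelled, and full digestion assumes every site is cut.
* Conservation scores are alignment-quality-bound: fragmentary orthologs
  are excluded row-wise, but misalignment is not detected.
* PSI models extrapolate poorly outside the composition of their training
  peptides; categories are relative to the training distribution, not
  absolute stability classes.
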