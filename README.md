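# degronkit

Offline degron analysis for R: motif scanning, tripartite context,
proteolysis simulation and terminal-peptide stability modelling.

## The problem

Most regulated protein degradation starts with a **degron** — a short linear
element that an E3 ubiquitin ligase recognizes. Degrons come in three
flavours by location: **N-degrons** (destabilizing N-terminal residues, e.g.
the Arg/N pathway's type-1 basic R/K/H and type-2 bulky hydrophobic
F/W/Y/L/I residues), **C-degrons** (C-terminal motifs such as -GG, -RG,
-EE), and internal motifs (APC/C D-box `RxxLxx[LIVM]x[ND]`, KEN-box, SCF
phosphodegrons). A motif alone rarely suffices: under the **tripartite
degron model** a functional degron combines (1) the primary motif, (2)
nearby ubiquitination-site residues — K, and also C/S/T — as *secondary
degrons*, and (3) a flexible intrinsically disordered region (IDR) as the
*tertiary degron*. Proteolytic cleavage complicates the picture further: a
cut creates **neo-termini** that can expose entirely new N-/C-degrons, as
happens when deubiquitinases mature ubiquitin-fold precursor proteins by
cutting after a diglycine motif.

degronkit packages this whole analysis for offline, scriptable use: every
function takes a data frame and returns a tibble, so analyses compose with
the pipe.

## What it computes

- **Sequence I/O and validation** — FASTA and single-chain PDB queries
  (B-factor column read as pLDDT for predicted models), a strict
  canonical-alphabet check, an exclusive 40 000-residue length limit, and
  initiator-Met variants (positions always reported in full-length
  coordinates).
- **Motif scanning** (`scan_degrons()`) — motifs carry a location class
  (`N_TERMINAL` / `C_TERMINAL` / `INTERNAL`); anchoring is enforced by the
  scanner, and both Met variants are screened. Patterns use a restricted
  dialect: residue literals, `x` wildcard, `[KR]` / `[^P]` classes, bounded
  repeats `{n}` / `{m,n}` — no anchors, alternation or unbounded
  quantifiers, so every match is enumerable. A documented starter motif set
  ships with the package (`builtin_motifs()`); bigger tables load from
  TSV/JSON via `load_motifs()`.
- **Terminal analysis** — Gravy (mean Kyte–Doolittle hydropathy) of the
  terminal 15 residues and the Arg/N-end-rule class of the N-terminal
  residue.
- **Structural context** — RSA = ASA / MaxASA (Rost & Sander 1994 maxima,
  clamped at 1); secondary structure via a pluggable DSSP-style adapter;
  disorder from structure pLDDT (disordered < 70) or from sequence
  (disordered > 0.5; built-in windowed hydropathy/net-charge heuristic, or
  any external predictor via an adapter function); IDRs as maximal
  disordered runs of at least 10 residues.
- **Tripartite reports** — every K/C/S/T within ±15 residues of a primary
  match with per-site context, the nearest IDR per site (distance 0 inside;
  ties break N-terminal), plus PTM and missense-mutation overlays from
  user-supplied TSV tables.
- **Proteolysis** (`find_cleavage_sites()`, `digest()`,
  `neo_degron_screen()`) — 35 built-in protease rules with
  PeptideCutter-compatible subsite semantics (P4–P2′ context patterns with
  exception vetoes), user cleavage motifs/sites and experimental site
  tables; full or single-site digestion; neo-termini re-screened for
  degrons and N-end-rule class.
- **Conservation** (`score_conservation()`) — four per-match scores over a
  user MSA, all in [0, 1]: anchored presence (s1), windowed presence (s2 ≥
  s1), column identity (s3) and 1 − normalized column entropy (s4).
- **PSI stability models** (`train_psi()`, `predict_psi()`) — gradient-
  boosted regression of the Protein Stability Index of terminal 23-mers
  from physicochemical descriptors (composition, Gravy, net charge,
  molecular weight, aromaticity, pI, aliphatic index) over the full peptide
  and the terminal 10/8/6/4/2 residues; 90:10 train/test split, 5-fold
  random-permutation CV, and five stability categories cut at the
  20/40/60/80th percentiles of the training PSI distribution. `tidy()` and
  `glance()` methods summarise fitted models; `autoplot()` draws
  observed-vs-predicted and disorder tracks.

`run_pipeline()` orchestrates all stages per query type and
`export_report()` writes a TSV bundle (one file per section plus a JSON
manifest) or a single JSON document. A thin CLI lives in
`inst/exec/degronkit` (`scan`, `cleave`, `run`).

## Worked example: precursor maturation exposes an N-degron

`synthetic_sde2_precursor()` builds a synthetic ubiquitin-fold precursor
(the UBL core is the human ubiquitin sequence; the C-domain is designed):
the UBL is closed by a diglycine at residues 76–77 and followed by a lysine
at 78 — the architecture of DUB-matured precursors whose released C-domain
is cleared through the Arg/N pathway.

```r
library(degronkit)

prot <- synthetic_sde2_precursor()
events <- find_cleavage_sites(prot, motif = "GG")
#>   protein_id     position source     enzyme
#> 1 SDE2_SYNTHETIC       77 user_motif <NA>

fragments <- digest(prot, events)
neo <- neo_degron_screen(fragments, builtin_motifs())
neo[, c("fragment_id", "neo_n_residue", "neo_n_class", "n_gravy", "c_gravy")]
#>   fragment_id           neo_n_residue neo_n_class   n_gravy c_gravy
#> 1 SDE2_SYNTHETIC_1-77   <NA>          <NA>            0.733 -0.0467
#> 2 SDE2_SYNTHETIC_78-161 K             type1_primary  -1.69  -0.98
```

Cutting the bond 77|78 yields the UBL (1–77) and a C-fragment starting at
residue 78 whose neo-N-terminal lysine is a type-1 primary destabilizing
residue — an Arg/N degron revealed only after cleavage. A stability model
trained on synthetic PSI data then scores the fragment termini:

```r
d <- synthesize_psi_dataset(2000, terminus = "C", sigma = 0.1, seed = 1)
model <- train_psi(d, cv_folds = 0L)
glance(model)
#>   terminus r2_test rmse_test n_train n_test
#> 1 C          0.992     0.108    1800    200

predict_psi(model, proteins = prot)
#>   protein_id     peptide                 terminus   psi category
#> 1 SDE2_SYNTHETIC VKSMDNPFVSRALEWAAKHQDES C        -1.66 unstable
```

Lower PSI means less stable; categories come from the training-distribution
quantiles.

## Data schemas

Tab-separated, header row, UTF-8 throughout: motifs (`motif_id`, `name`,
`pattern`, `location_class`, `pathway`, `source`); PTMs (`protein_id`,
`position`, `ptm_type`, `source`); mutations (`protein_id`, `position`,
`ref`, `alt`, `source`); E3 interactors (`protein_id`, `e3_id`, `source`);
cleavage sites (`protein_id`, `position`, `enzyme`, `physiological`,
`source` — non-physiological rows skipped by default); stability tables
(`protein_id`, `terminus`, `peptide`, `psi`). See the methods vignette
(`vignettes/degron-analysis.Rmd`) for the modelling details and design
decisions.
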