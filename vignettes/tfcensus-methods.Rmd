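---
title: "Methods: TF classification, census algebra and co-expression modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF classification, census algebra and co-expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcensus)
```

This vignette documents the models and procedures implemented by
`tfcensus`, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data generators do and do not
emulate.

## TF identification and family classification

A transcription factor is operationally a gene whose representative
protein carries at least one DNA-binding domain (DBD) hit passing its
family's e-value threshold. The rule engine works on hmmscan per-domain
tables (`read_domtblout()`); it never runs HMMER itself, which keeps the
package free of external binaries and makes classification a pure
function of its inputs.

**Thresholds.** The screened statistic is the full-sequence e-value,
the convention of the TF databases the per-family thresholds are
borrowed from; a switch (`evalue_field = "ind_domain"`) screens the
per-domain independent e-value instead, since domain tables carry both
and practice varies. The boundary is inclusive: `e <= t` passes, reading
"screened with threshold t" as a cutoff *at* the stated value. Defaults:
`1e-4` for most families, `1e-2` for bHLH, `1e-3` for HMG_box,
Homeodomain, zf-BED and zf-C2H2, `1e-20` for zf-CCCH. The shipped rule
set maps 85 Pfam DBD accessions to families and superfamilies; it also
carries the BTB accessory domain flagged `is_dbd = 0`, which can
participate in compound rules but can never by itself make a gene a TF.
Rule families are allowed to end up with zero members (zf-CCCH does, in
the packaged census).

**One TF = one gene.** Proteomes are collapsed to one representative
protein per gene before classification: the longest isoform, ties broken
by the lexicographically smallest protein id. This deterministic policy
replaces sequence-identity clustering; its intent (count each locus
once) is the same, and it requires no external tool.

**Conflict resolution.** Where a gene has passing hits from several
families the assignment is fully deterministic, in this order:

1. *Compound rules.* If passing hits cover every required family of a
   compound rule, the gene takes the rule's host family and subtype.
   The shipped rule defines ZBTB: BTB + zf-C2H2 on one gene is a
   zf-C2H2-family TF of subtype ZBTB.
2. *Smallest e-value* among passing DBD hits, then *larger bit score*,
   then *alphabetical family name*.

All passing DBD families are preserved in `candidate_families` as an
audit trail, so downstream users can quantify how often the tie-break
mattered. The source survey does not state its conflict policy; this
ordering is this package's construction, chosen to be reproducible and
to respect the explicit compound-architecture definition.

## Census algebra

All comparative set algebra operates on a families x species count
matrix. *Presence* always means count > 0 — no minimum-count notion is
introduced, because the comparisons being reproduced (shared families,
exclusive-shared sets) are presence/absence statements. Superfamily
membership (bZIP, NF-Y, ETS, bHLH, Homeobox, IRF, STAT, zinc finger,
Nuclear Receptor, MH1) is carried as metadata only; set algebra stays at
family level. Percentages (`family_fraction()`) are rounded to two
decimals only at the reporting layer.

The two published summary tables ship as plain-text fixtures
(`load_paper_tables()`), cell-for-cell as printed. One printed row (PBC
in the module table) has cells summing to 1 against a printed row total
of 0; the fixture keeps the printed values and reports the row in
`table2_inconsistent` rather than silently correcting either number.
The module table also prints 547 network genes against 553 census genes
(six genes presumably never expressed), and uses slightly different
family labels ("HLH", "Hormone_recepter"); fixtures preserve the print.

## The co-expression network

The network is the standard weighted-correlation construction,
implemented from first principles rather than wrapped:

* **Normalization**: `log10(FPKM + 1)` elementwise. Replicate columns
  (`<stage>_<k>`) are averaged per stage before correlation; the
  reference design is 7 stages x 3 replicate libraries.
* **Correlation**: Pearson across the (at least 3) stage columns.
  Zero-variance genes are flagged and decorrelated (row/column set to
  0) instead of propagating `NA`.
* **Adjacency**: unsigned `a_ij = |c_ij|^beta` by default, signed
  `((1 + c_ij)/2)^beta` by option. Unsigned is the default because the
  reference analysis does not state a sign convention and unsigned is
  the historical default of the method. `beta = 12` is the reference
  soft power.
* **Topological overlap**:
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
  `l_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`,
  computed with one matrix product and clamped to [0, 1] against
  floating-point dust. Tests require agreement with a literal
  double-loop evaluation to 1e-10.
* **Module detection**: average-linkage clustering on `1 - TOM`, cut at
  `cut_height` (default 0.99) times the maximum merge height, clusters
  below `min_module_size` relabeled grey, survivors colored by
  descending size (turquoise, blue, brown, ...; ties by first gene
  index). The static cut approximates the least aggressive regime of
  dynamic tree cutting (`deepSplit = FALSE`): that regime splits only
  well-separated top-level branches, which is exactly what a single
  height cut below the top merges does. A `1e-10` floor on the cut
  guards the degenerate case where all profiles coincide and every
  merge height is numerical noise. `min_module_size = 300` is the
  genome-scale default; synthetic runs in the tests use 20, scaled to
  their few-hundred-gene instances.
* **Developmental groups**: each module's mean log-profile peak stage
  maps to Group I (2–8 cells, gastrula, neurula), II (tailbud) or III
  (hatched larva, tail-regressed larva, juvenile); ties take the
  earlier stage, so a perfectly flat module lands in Group I. The
  module eigengene (first PC of the standardized submatrix, sign fixed
  toward the mean profile) is exposed for diagnostics but group
  assignment uses the mean profile, which is simpler and has no sign
  ambiguity.

Module *counts* are parameter- and input-dependent: the reference
analysis ran on all expressed genes of 21 libraries and read TF
memberships off afterwards, whereas this package networks whatever
matrix it is given. A nine-module outcome is therefore not a target the
package asserts; what it asserts (and tests) is recovery of *planted*
structure.

Network inclusion ("expressed in at least one stage") is FPKM > 0 in
any stage by default and is distinct from the *expressed* call
(FPKM > 10) used for the maternal proportion and onset analysis; both
thresholds are arguments.

## Hox temporal collinearity

"Initially expressed" is formalized as the earliest stage with
FPKM > 10 — the same cutoff as the expressed call, since the source
never defines onset numerically; the threshold is an argument.
Collinearity between genomic order and onset order is scored with
Kendall tau-b, the tie-corrected variant, because onset stages are
heavily tied ordinal data (seven possible values); when a ranking is
constant, tau-b is undefined and 0 is returned. Subcluster detection
enumerates contiguous windows only (the phenomenon being modeled is a
contiguous run), requires every member to have an onset, demands
|tau| = 1, and reports only maximal windows: a window is dropped if a
one-gene extension also qualifies. Reversing the genomic order provably
flips every orientation, and the tests assert it.

## Enrichment and qPCR arithmetic

Term enrichment is the one-sided hypergeometric upper tail
`P(X >= k)` per term, with Benjamini–Hochberg adjustment across the
tested terms. Terms with zero background genes are skipped and excluded
from the BH family size. The reference analysis used a web tool without
naming its test; the hypergeometric/BH pair is the standard such tools
wrap and is documented here as this package's choice. No GO-graph
propagation is performed: annotations are used exactly as supplied.
Relative qPCR expression is `2^-ddCt` with `dCt = Ct_target -
Ct_reference` per condition; the arithmetic satisfies
`ddct(a, b) * ddct(b, a) = 1`, which the tests check.

## What the generators emulate — and what they do not

Every pipeline input has a seeded generator returning the emitted files
*and* the ground truth used to write them; determinism (same seed, same
bytes) is part of the contract and is tested.

* `simulate_domtblout()` plants per-family DBD hits with e-values drawn
  log-uniformly below threshold, compound BTB + zf-C2H2 genes, 1–4
  isoforms per gene with hits on the longest, and decoys whose every
  hit is at least 10x above threshold — so no inclusive/exclusive
  boundary convention can flip a decoy. The default family mix is
  proportional to the packaged *S. clava* census. FASTA sequences are
  random residues of the stated lengths; nothing about sequence content
  is realistic, only the annotation geometry.
* `simulate_expression()` gives each planted module a Gaussian bump on
  the log10 scale (amplitude 2, width 0.6 stages, baseline 0.2) at its
  peak stage, plus independent per-gene noise calibrated so the
  expected within-module correlation equals the requested value;
  FPKM = 10^x − 1 clipped at zero, so normalization recovers the latent
  structure exactly up to clipping. The width is deliberately narrow:
  stage-restricted modules are near-orthogonal to each other, which is
  what the grouped, stage-peaked modules being emulated look like. A
  wide-bump variant makes distant-peaked modules strongly
  anti-correlated, and an unsigned network then genuinely cannot
  distinguish a module from its mirror — a real limitation of unsigned
  networks, not of the detector, and one reason the signed option
  exists.
* `simulate_hox_cluster()` plants onsets collinear, anti-collinear or
  shuffled (rejection-sampled so no length-3 perfect window survives).
* `simulate_annotation()` plants one term over-represented in the
  target at a stated fold against independent decoy terms.

Passing recovery tests on these fixtures shows the algorithms do what
they claim on data matching their assumptions. It does not show
robustness to what real data adds: library-size artifacts, correlated
noise between adjacent stages, families whose DBDs drift below Pfam
gathering thresholds, or modules without clean single peaks.

## Problem sizes and numerical conventions

The test and acceptance runs use: classifier instances of up to 20
hits against exhaustive enumeration; 120 planted TFs + 80 decoys + 12
ZBTB for end-to-end recovery; 30-gene random networks for the TOM
oracle (1e-10); 150 genes / 3 modules noiseless and 300 genes / 4
modules at within-correlation 0.8 over 20 seeds for module recovery
(min_module_size 20); hypergeometric backgrounds up to N = 60 for pmf
summation (1e-12). These sizes make the whole suite run in well under a
minute while leaving each check at full strength — the oracles are
exact, so size buys nothing but time.

Other conventions: domain-hit envelope coordinates stay 1-based
inclusive on the protein exactly as the per-domain table prints them,
while genomic loci use the BED convention (0-based, half-open)
throughout; Pfam accession versions are stripped on read so rule joins
survive Pfam release drift; all reader round-trips are bitwise.

## Known limitations

* The static height cut is a limiting approximation of conservative
  dynamic tree cutting; trees whose module joins are not well separated
  from the top merge will under-split. The `deep_split` regime is
  deliberately not implemented.
* Module–trait statistics, eigengene-similarity merging and scale-free
  fit diagnostics for choosing beta are out of scope.
* Expansion/contraction is reported as raw count differences; no
  birth–death significance model is fitted.
* Paralog-group assignment for cluster genes is an input (it comes from
  phylogenetics), never computed.
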