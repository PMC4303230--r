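---
title: "ctDNA fragment-size, copy-number and clonality analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctDNA analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdx)
```

This vignette records the models behind each stage of the package, the
tunable parameters with their defaults and rationale, what the synthetic
generator does and does not emulate, and the design choices made where
the methodology was genuinely open.

## 1. Fragment-size model

Cell-free DNA fragment lengths reflect nucleosomal protection during
apoptotic digestion: core particle (~142 bp) plus linker (~20 bp) gives
component centers fixed at **162, 324 and 486 bp** for mono-, di- and
tri-nucleosomal fragments. The generator draws fragment lengths from a
Gaussian mixture at these centers with **component spread 15 bp**
(electropherogram peaks are reported only approximately, near 160 and
310 bp; a 15 bp spread reproduces peaks of that width without overlap
between bands), adds measurement jitter (`noise_sd`, default 3 bp, in
quadrature), and bins 20,000 fragments on a 1-bp grid from 50 to 600 bp.

Classification parameters:

* **Bands** `[85, 250)` and `[250, 450)` bp, half-open, configurable.
  One published passage gives the apoptotic band as 85–230 bp while the
  results sections use 85–250 bp; the 85–250 bp definition is adopted
  and the edges are arguments, so the alternative is one call away.
* **`long_band_threshold` = 0.05.** No numeric rule is published; the
  mononucleosomal tail mass beyond 250 bp is below 10⁻⁴ (the band edge
  sits > 5 σ above the 162 bp mode) while a 10% dinucleosomal admixture
  puts ≈ 9% of mass there, so 5% separates the classes with a wide
  margin on both sides.
* **Peak detection**: running-mean smoothing (half-width 4 grid points),
  local maxima with height ≥ 10% of the global maximum, maxima closer
  than 50 bp merged to the higher one. Electropherogram peaks are read
  visually in practice; this is the simplest deterministic
  operationalization.

A biphasic call requires *both* the long-band mass threshold and a
detected peak inside 250–450 bp, which keeps heavy smooth tails (no
distinct dinucleosomal population) monophasic.

## 2. Copy-number model

Read counts over the bin grid are multinomial with bin weight
proportional to `width × (2 + f·δ)/2`, where `f` is tumor fraction and
`δ` the summed integer copy-number delta of events covering the bin
midpoint. Ratios are `log2((c_i/Σc)/(b_i/Σb))`, median-centered;
zero-count bins are floored at half a read (at the depths used,
zero-count bins are practically absent).

* **Segmentation** is exact optimal partitioning per chromosome,
  minimizing `SSE + λ·k` by dynamic programming — not greedy binary
  splitting, because the test contract requires equality with exhaustive
  search. Default `λ = 2σ̂² log(n)` (BIC-like) with
  `σ̂ = median|Δlog2| / (0.6745·√2)`, robust to the piecewise-constant
  signal itself.
* **Calling cuts ± 0.2 log2.** The source method publishes no cuts. A
  single-copy event at tumor fraction f sits at log2((2+f)/2), so ±0.2
  puts the call boundary near f ≈ 0.3: plasma at 2–3% AF is always
  balanced, tumor tissue (f ≥ 0.5) always unbalanced, and the
  detectability tests are asserted only at f = 0.02–0.03 and f = 0.35,
  where any reasonable cut gives the same answer.
* **`min_aberrant_fraction` = 0.05**: a profile is unbalanced when ≥ 5%
  of bins are non-neutral. Arm-level events each cover 1–4% of the
  genome, so a single arm does not flip a profile but any realistic
  multi-arm tumor signature does.
* **Distances** use the literal 3-level "copy number status" encoding
  (loss = −1, neutral = 0, gain = +1) under the Manhattan metric, with a
  `use_log2` flag for the continuous alternative, since the published
  description does not state how status was discretized.
* **Complete-linkage clustering** is implemented in-package with a
  deterministic tie-break (lexicographically smallest label pair) so
  dendrograms are reproducible; Newick serialization goes through `ape`.

## 3. Synthetic cohort: the stated world

The cohort generator fixes the 2×2 composition (25 biphasic-detected, 7
biphasic-undetected, 3 monophasic-detected, 36 monophasic-undetected; 71
samples) and draws per-sample inputs so the default classifiers realize
that composition:

* tumor fraction ~ U(0.45, 0.65) for CNA-detected samples, U(0.01,
  0.03) for undetected ones. No cohort tumor fractions are published;
  these ranges are a free choice of the generator, placed far on either
  side of the ±0.2-cut detection boundary so the planted composition is
  realized essentially surely rather than with a few-percent flip rate.
* dinucleosomal weight ~ U(0.15, 0.35) for biphasic samples, 0 for
  monophasic ones — again clearly separated from the 5% mass threshold.
* each detected sample carries a random subset (inclusion probability
  0.8, minimum 4) of the recurrent breast-cancer archetype: losses of
  1p, 8p, 13q, 16q and gains of 1q, 8q, 16p, 17q.
* a binary liver-metastasis covariate is correlated with detectability
  through a configurable log-odds (default 2) — capability only; no
  published per-patient value is reproduced.

Sequencing is emulated at the bin level (multinomial), not the read
level: no FASTQ, no GC or mappability bias (a baseline hook exists — any
expected-count table can replace the uniform baseline), no
sequencing-error model beyond binomial sampling at planted SNVs. A green
cohort test therefore establishes that the *analysis* chain recovers a
planted composition under idealized noise, not that real plasma would
behave this way.

Tests and the acceptance script run hg19-proportioned genomes at
600–1,000 bins instead of the full 50,000 so the whole suite finishes in
seconds; per-bin depth is kept in the same regime (~100–400 reads/bin)
as shallow WGS binned at full resolution, and the full model remains one
argument away (`make_genome_model("hg19")`).

## 4. Index patient fixture

Eight SNVs are planted with the published allele fractions: five truncal
genes at approximately constant AF everywhere, DDR2 at 36.4% in tumor A
versus 15.3/16.6% in tumors C/D, MLL3 in A (14.1%) and the lymph nodes
(18.9–24.2%; the unpublished LN17 value is set to the midpoint 21.55%),
PIK3CA in lymph nodes only. The exome-cascade fixture plants these
eight candidates among per-sample somatic backgrounds spanning 716
(tumor C) to 1,589 (LN15) calls, germline contamination, non-exonic
calls, and sample-private driver-gene decoys, so every cascade step
removes something and the audit trail is informative. The germline
table holds 21,741 calls with 20,749 in the known-variant set (992
novel) — the partition arithmetic is computed, the totals are the stated
world.

Copy-number events: all lesions share gains of 1q and 8q and losses of
6q, 8p, distal 11q (the distal half of the arm) and 17p; tumor A adds a
private 20q gain, the lymph nodes a shared 16q loss, and the CTC pools
additionally the 1p loss novel to the CTCs. The private/derived events
are inventions of the generator — the published record says only that
profiles were highly similar with the clades resolvable by clustering —
sized so that complete linkage reproduces the published grouping (C with
D; lymph nodes together; CTCs together, nearest the lymph nodes).

Plasma samples carry tumor fraction *and* per-SNV true AF drawn in
[0.02, 0.03]. A heterozygous clonal SNV in a diploid region implies
AF = f/2; the source text uses AF and tumor fraction interchangeably and
states the 2–3% figure as both the measured AF and the balanced-profile
regime, so the fixture plants AF = f and leaves the f/2 adjustment to
the reader (it changes nothing qualitative: both readings are far below
the ~10% detection limit). The measured per-ml mutant-fragment
concentrations (6,320 / 8,524 / 4,419) are inputs, not simulations.

## 5. Clonal inference choices

* Presence threshold = the 1% deep-seq detection cutoff.
* Lesions with identical presence patterns merge into one node; the
  three lymph nodes form a single node, as drawn in the source figure,
  and the C/D tie ("C and/or D") is left unresolved by design.
* **`increase_ratio` = 1.5** compares *node-mean* AFs along each edge.
  DDR2 (36.4 vs 15.95 mean, 2.3-fold) and MLL3 (21.5 mean vs 14.1,
  1.5-fold) are flagged at the default; flagging the weakest single-
  lesion contrast (LNA 18.9 vs 14.1, 1.34-fold) would need a ratio
  ≤ 1.3, which would also start flagging binomial noise at depth 10⁴.
  The default favors specificity.
* No subclonal deconvolution or copy-number-adjusted cellularity: the
  method is set containment plus AF comparison, deliberately.

## 6. AF quantification choices

The whole-body mutant-fragment count is `N_total = per_ml × v × W` with
**v = 60 ml/kg** — the published range is 60–70 ml/kg, and 60 is the
unique value in that range reproducing all three published totals from
the published per-ml averages at W = 60 kg. The per-ml reading of the
published averages is itself inferred from that arithmetic consistency
(the unit is configurable). Totals are additionally reported rounded to
2 significant figures (round-half-even, R's `signif`) because that is
the precision of the published numbers. The 16-minute ctDNA half-life
is carried as metadata and drives no computation; the "number of tumor
cells that released ctDNA" interpretation is exposed as an alias of
`N_total`, not a separate model.

## 7. Cohort statistics choices

Pearson χ² without continuity correction by default (the published
analysis says only "chi-squared test"; the p < 0.0001 conclusion holds
under either convention), df fixed at 1, error on any zero margin. The
permutation-null check in the tests exploits that permuting detection
labels with fixed margins makes the biphasic-detected cell
hypergeometric, and compares under the mid-p convention — against a
discrete null the uncorrected asymptotic p cannot agree to Monte-Carlo
error, and the residual discreteness bound (~0.08 at n = 80) is part of
the test, not a claim about the method.

## 8. Numerical and degenerate-input conventions

Bin coordinates are 0-based half-open; variant positions 1-based.
Band masses interpolate linearly at band edges, making them additive
over adjacent bands. Segment ties in the DP resolve to the earliest
breakpoint; clustering ties to the lexicographically smallest pair.
Single-leaf dendrograms serialize as `label;`. AF matrices whose
presence sets form no chain return the Hasse diagram of whatever partial
order exists (possibly a forest). All randomness flows through
explicit seeds (scoped with `withr::with_seed`, never the global RNG
state); sub-seeds are derived from the master seed by a 31-bit string
hash so adding a sample never shifts another sample's draws.

## 9. Known limitations

* Bin-level multinomial noise understates real shallow-WGS dispersion
  (GC waves, mappability); detectability results transfer only
  qualitatively.
* The fragment-size generator emulates electropherogram densities, not
  BAM insert sizes; no reader for proprietary sizing formats.
* The variant cascade consumes call tables; it does not re-implement
  the upstream callers, and indels are out of scope.
* Clonal ordering assumes presence/absence is called correctly at the
  1% cutoff; heavily unbalanced designs (depth ≪ 10⁴ at AF near the
  cutoff) will fragment the tree.
* The cohort's published mean plasma AF (3.7% ± 1.6%) and the
  liver-metastasis association (P = 0.002) depend on per-sample
  supplementary values that are not published in the text; the package
  provides the capability but does not claim those numbers.
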