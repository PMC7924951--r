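---
title: "Methods: binding-site switch classification and loop connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site switch classification and loop connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", message = FALSE)
library(switchloop)
library(dplyr)
```

## The analysis problem

`switchloop` implements the downstream computations used to describe a
signalling-driven *switch* in transcription-factor occupancy, in the
setting of nephron progenitor cells (NPCs) induced by raising the dose
of the GSK3 inhibitor CHIR99021: at low dose, repressive TCF/LEF family
factors (Tcf7l1/Tcf7l2) occupy Wnt-responsive enhancers; at high dose,
rising β-catenin replaces them with the activating factors Tcf7/Lef1 at
largely the same DNA elements. The package covers five stages, each a
plain function over tibbles:

1. **Reproducible-peak filtering** — windowed tag counting, fold
   enrichment, and threshold filters for ChIP-seq and ATAC-seq peak
   sets.
2. **Switch classification** — partition of two condition-specific peak
   sets into *lost* (set 1), *switch* (set 2) and *de novo* (set 3)
   classes by a center-distance rule, with motif-stratified overlap
   fractions.
3. **Differential statistics** — a documented negative-binomial Wald
   test, TPM conversion, and the standard TPM/fold-change/p-value
   calling rules for differential expression and accessibility.
4. **Loop connectivity** — Hi-C loop replicate reconciliation,
   conserved-vs-specific loop comparison, and the
   peak → anchor → partner-anchor → TSS chain with summary
   percentages.
5. **Synthetic data** — generators that plant ground truth for every
   stage, so the whole pipeline is testable without any sequencing
   data.

## Coordinate conventions and center-distance matching

All intervals are 0-based half-open (BED convention), since every
interval that enters or leaves the package travels through BED-family
files. Each interval has a *center*: a summit supplied by the upstream
peak caller (narrowPeak column 10) when available, otherwise the
integer midpoint `floor((start + end) / 2)`.

Two peaks are the same site when their centers lie within **150 bp**
of each other on the same chromosome. The boundary is inclusive — a
distance of exactly 150 matches — because the rule is phrased both as
"within 150 bp" (match) and "beyond 150 bp" (unique), and the inclusive
reading satisfies both. Matching is **one-to-one**: candidate pairs are
ranked by distance, ties broken by the lower start coordinate (the key
is symmetric under swapping the two sets), and accepted greedily. This
makes mutual-nearest pairs win, makes the output deterministic, and
guarantees that after matching no unmatched peak from one side lies
within the threshold of an unmatched peak from the other.

Merging (used to build the accessibility-window universe) chains
greedily left-to-right over coordinate-sorted centers: a center within
150 bp of the current merged center is absorbed and the merged
coordinate becomes the midpoint of the two (floored on odd sums).
Multi-peak chains are not otherwise specified by the underlying rule,
so the chained-midpoint interpretation was fixed once; it guarantees
output centers are pairwise more than the threshold apart, hence the
operation is idempotent.

```{r match-demo}
low <- tibble::tibble(chrom = "chr1", start = c(900, 4900),
                      end = c(1100, 5100))
high <- tibble::tibble(chrom = "chr1", start = c(1000, 8900),
                       end = c(1200, 9100))
glance(classify_sites(low, high))
```

## Fold enrichment and the reproducibility filters

Fold enrichment of a window is the observed tag density over the
genome-average density:

$$\mathrm{FE} = \frac{c / L}{N / G}$$

with `c` the tag count within ±250 bp of the peak center, `L` the
window length, `N` the library size and `G` the effective genome
length. The window length for a ±250 bp window is **501 bp** (both
boundary positions included), and a window at exactly the background
expectation has FE = 1 — which is what "fold enrichment" should mean.
Tag positions are used as given (the 5′ ends reported upstream); any
fragment-shift model belongs to the peak caller, not here.

The filters mirror the standard practice for this kind of data and are
all **strict** inequalities; values exactly at a threshold are dropped:

| filter | rule |
|---|---|
| ChIP reproducible | `q < 1e-4` and FE `> 10` in *every* replicate |
| ChIP strong | FE `> 20` in every replicate |
| ATAC reproducible | FE `> 3` in all 3 replicates |
| differential expression | max group-mean TPM `> 5`, fold change `> 3`, NB `p < 0.05` |

"Both replicates" is generalised to "all replicates supplied" so ChIP
(2 replicates) and ATAC (3) share one code path.

## Motif scanning and stratified overlap

The PWM scan is a standard log-odds scan:
`score = Σ log2(p_i(base) / bg(base))` in bits, both strands (via the
reverse-complemented matrix), windows containing non-ACGT characters
skipped. A peak is motif-positive when any hit in its sequence reaches
the score floor. The stratified overlap then asks, separately for
motif-positive and motif-negative low-condition peaks, what fraction
fell in the switch class. No matrix is bundled: the scan consumes any
JASPAR-style PFM (`read_jaspar()`).

The hypergeometric overlap test (`overlap_significance()`) needs a
caller-supplied universe size; published overlap p-values of this kind
depend on that unstated universe, so the test is a tool for the user's
own universe definition, not a reproduction of any printed value. It
returns log10 p to survive genome-scale underflow.

## The negative-binomial Wald test

The original analyses ran DESeq2. This package implements a
deliberately simple, fully documented NB pipeline instead, and states
plainly that it is **not** numerically identical to DESeq2 (no LFC
shrinkage, no Cook's-distance outlier handling, no independent
filtering):

* **Normalisation** — median-of-ratios size factors over features with
  nonzero counts in every sample.
* **Fold change** — `log2((μ_B + 0.5) / (μ_A + 0.5))` on group means of
  normalised counts; the 0.5 pseudocount bounds the statistic for
  zero-count groups.
* **Dispersion** — method of moments per feature from within-group
  residuals on the normalised scale (`Var = ξμ + αμ²`, with
  `ξ = mean(1/s_j)` accounting for the Poisson-term inflation of
  normalised counts), floored at 1e-8. With 3 replicates per group the
  raw per-feature estimate is far too noisy for a normal-approximation
  Wald statistic — it would behave like a z-test with ~4 degrees of
  freedom and badly inflated type-I error — so the default shares
  information across features through a fitted mean-dispersion trend
  `α(μ) = a + b/μ` (raw estimates trimmed at the 1%/99% quantiles
  before the fit). This is the same reasoning that leads DESeq2 and
  edgeR to moderate dispersions; `dispersion = "per_feature"` exposes
  the unsmoothed estimator for study.
* **Test** — Wald statistic = LFC over its delta-method standard error,
  two-sided normal p-value, Benjamini–Hochberg adjustment.

The test is validated by *calibration*, not by matching published gene
counts (which depend on the raw sequencing data): under the null
simulation the fraction of raw `p < 0.05` must sit near 0.05, and
planted 8-fold effects at mean 100 must be recovered with high power.
A cross-check against DESeq2 on simulated data (fold-change correlation
and call overlap) runs in the test suite.

```{r nb-demo}
sim <- simulate_counts(sim_config(seed = 1, preset = "de_null",
                                  n_genes = 500))
fit <- nb_wald_test(sim$counts, sim$design)
glance(fit)
mean(tidy(fit)$p_value < 0.05)
```

TPM is the usual length-normalised unit: `rate = count / (length/1000)`,
scaled so every sample column sums to exactly one million. The
differential-expression fold change is computed on group-mean TPM with
a 0.5 pseudocount, and "TPM > 5" is applied to the larger of the two
group means — the published rules do not state the scale or the group,
so both choices are fixed here and exposed as arguments. The DAR
(differentially accessible region) cutoff defaults to adjusted
`p < 0.05` and is configurable, since the original thresholds live in
supplementary material that does not travel with the text.

## Loop reconciliation and the connectivity chain

Loops are anchor pairs in canonical order
(`(chrom1, start1) ≤ (chrom2, start2)`). Two loops match when **both**
anchor centers lie within **10 kb**, compared anchor-to-anchor without
swapping, boundary inclusive. Replicate reconciliation keeps every
replicate-1 loop with at least one qualifying replicate-2 partner and
annotates the nearest; condition comparison uses the same rule with
one-to-one greedy matching so the shared/specific partition reconciles
exactly with the input sizes. The condition-level comparison reuses the
10 kb replicate tolerance, which the source methods leave unstated.

The connectivity chain then runs on the induced condition's loops:

1. a peak sits in a loop anchor when its center is within **5 kb** of
   the anchor center;
2. the peak connects to a gene when a TSS lies within **15 kb** of the
   center of the *opposite* anchor (strand-agnostic, as the rule is a
   pure distance);
3. each TSS-connected peak is attributed to *conserved* loops when at
   least one of its connecting loops is shared between conditions,
   otherwise to condition-specific loops — ties go to conserved,
   matching the framing that conserved connectivity is the headline
   fraction.

Percentages are successive ratios rounded to the nearest integer; raw
fractions are always retained in the report object.

```{r chain-demo}
u <- simulate_loop_universe(sim_config(seed = 1))
lowL <- filter(u$loops, condition == "low", replicate == 1)
highL <- filter(u$loops, condition == "high", replicate == 1)
res <- run_loop_pipeline(u$peaks, lowL, highL, u$tss)
res$report
```

## What the synthetic generators emulate — and what they do not

The generators exist so that every stage has planted, machine-checkable
ground truth.

* `simulate_peak_landscape()` lays planted sites on a fixed grid
  (5 kb spacing over 2 × 50 Mb by default), draws per-replicate fold
  enrichments above the filter thresholds for planted-pass sites and
  below for planted-fail sites, and keeps q-values unambiguous
  (passing in (0, 1e-5), failing in (1e-3, 1)). The `switch` preset
  plants 240 lost / 160 switch / 200 de novo sites with an exact
  integer motif structure — 100 motif-positive low-condition sites of
  which 73 sit on switch sites — chosen as the smallest round design
  satisfying `71·S − 29·L = 4400`, so the stratified fractions are
  0.73 and 0.29 *by construction*, not by tuning.
* `simulate_counts()` draws NB counts with log-uniform size factors in
  [0.5, 2]; `de_null` (2000 features, 3+3 samples, mean 100,
  dispersion 0.1) and `de_power` (dispersion 0.05, 200 features at an
  8-fold change) are the calibration and power scenarios.
* `simulate_loop_universe()` lays out non-overlapping loop blocks
  (200 kb anchor span, 280 kb stride), emits shared loops in both
  conditions and specific loops in one, re-jitters replicate copies,
  and plants the connectivity chain with peaks 2 kb from host anchors
  and TSSs 8 kb from partner anchors. The `chain` preset plants the
  published chain 5530 → 1573 → 647 → 371 exactly.

Jitter is Gaussian (truncated at chromosome bounds) with SD 0 by
default: noiseless planting is the baseline and jitter is the
robustness dial used by the recovery tests (at 20 % of each tolerance —
30 bp for the 150 bp rule, 2 kb for the 10 kb rule — recovery stays
above 99 %). What the generators do **not** emulate: read-level noise,
genome sequence content, GC or mappability structure, correlated
replicates, overdispersion heterogeneity across peaks, or loop-calling
artefacts. Passing tests therefore demonstrate that the *rules* are
implemented exactly and behave continuously under coordinate noise —
not that the pipeline is robust to everything real data does.

## Numerical and design notes

* Midpoints and merged coordinates floor on odd sums; centers are
  integers throughout.
* Tie-breaks in every matcher are deterministic and label-swap
  symmetric (distance, then min/max start coordinate).
* `overlap_significance()` works on the log scale; `p_value = 0` simply
  means below double precision.
* Degenerate inputs return empty, correctly-typed tibbles (empty loop
  file → all-zero report), never errors, while malformed records
  (negative counts, inverted intervals, missing q-values) are hard
  validation errors with the offending line reported by the readers.
* Problem sizes in the test suite (up to ~150 peaks / 60 loops per
  brute-force oracle instance, 1000 planted sites or loops for the
  recovery checks, 2000 features for calibration) were chosen to keep
  the whole suite around half a minute while leaving the estimates'
  Monte-Carlo error well inside the asserted margins.

## Known limitations

* The NB test is a calibrated stand-in pipeline, not a DESeq2
  re-implementation; do not expect identical p-values on real data.
* Peak–gene assignment by regulatory-domain rules, motif discovery,
  loop calling and GO enrichment are out of scope; the package starts
  from called peaks, called loops and count tables.
* The TSS search is strand-agnostic; promoter directionality is the
  caller's concern.
* Whether the original 150 bp matching was mutual-nearest is unknown;
  only the deterministic mutual-nearest variant is implemented, and on
  well-separated sites (spacing ≫ threshold) the two coincide.
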