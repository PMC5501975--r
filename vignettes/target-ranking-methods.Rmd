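---
title: "Methods: multi-cohort miRNA target ranking and drug-synergy analysis"
author: "mirTargetRank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort miRNA target ranking and drug-synergy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTargetRank)
```

## The scientific problem

An oncogenic microRNA (oncomiR) such as miR-21-5p represses its target
mRNAs by base-pairing of its *seed* (positions 2--8 from the 5' end)
with sites in the targets' 3'-UTRs. Candidate targets of a
tumor-upregulated oncomiR are therefore expected to show three
independent signatures at once:

1. **Predicted seed sites** in their 3'-UTR (a consensus over several
   prediction criteria),
2. **Downregulation in tumors** relative to normal tissue, consistently
   across independent patient cohorts, and
3. **Anticorrelation** with the miRNA's expression across samples in
   which both were measured ("matched samples").

This package implements that composite screen as a reusable pipeline,
together with the downstream drug-synergy analysis (median-effect /
combination-index) used when a candidate target's pathway is tested
pharmacologically, and a log-odds PWM scanner for transcription-factor
sites (e.g. E2F) in the miRNA's own promoter.

## Per-cohort statistics

For each cohort and gene the pipeline computes:

* **Permutation tumor-vs-normal p-value.** Statistic: difference of
  group means of log2 expression. When the number of distinct label
  assignments $\binom{n}{n_T}$ is at most `exhaustive_limit` (default
  20,000) the assignment space is enumerated and the p-value is the
  exact two-sided tail fraction; otherwise $B$ = `n_perm` (default
  10,000) seeded resamples are drawn and the add-one estimate
  $p = (b+1)/(B+1)$ is used, which is never 0 and remains a valid
  p-value. The difference-of-means statistic was chosen as the
  standard, assumption-light choice for a two-group comparison of
  continuous expression; the test is two-sided via $|statistic|$.
  In the genewise path, Monte-Carlo assignments are drawn per block of
  100 genes (with a per-block seed) rather than shared across all
  genes: a single shared resample set would give all genes a common
  Monte-Carlo error component and measurably inflate the variance of
  the genewise p-value distribution under the null.
* **FDR.** Benjamini--Hochberg step-up across the analysed gene set
  (`stats::p.adjust`).
* **log2 fold change.** `mean(tumor) - mean(normal)` of log2
  expression; inputs are assumed already on the log2 scale (a
  `log2(x+1)` pre-transform is the caller's responsibility for
  raw-scale data).
* **Pearson anticorrelation.** On the matched-sample subset, $r$ and a
  two-sided p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$
  degrees of freedom; at least `min_matched` (default 5) complete pairs
  are required, otherwise the correlation fields are reported absent.
  A perfect $|r| = 1$ reports the numerical floor (1e-300), never 0.

## Consensus seed-site prediction

External target-prediction web services cannot be reproduced offline,
so the "number of predicting programs" vote is emulated by six seed
stringency modes, most to least stringent:

| mode | fires when the UTR contains at least |
|------|--------------------------------------|
| 1 | an 8mer site (reverse complement of miRNA 2--8 + A opposite position 1) |
| 2 | a 7mer-m8 (match to positions 2--8) or stricter |
| 3 | a 7mer-A1 (match to 2--7 + the A1 anchor) or stricter |
| 4 | a 6mer (match to 2--7) or stricter |
| 5 | an offset-6mer (match to 3--8) or stricter |
| 6 | a hexamer match to 2--7 allowing one G:U wobble, or stricter |

Each mode is *cumulative* over the stringency order, so the vote count
is monotone by construction: a planted 8mer scores 6/6, a plain 6mer
3/6. The default consensus threshold is 5 of 6 votes, mirroring the
"at least five programs" convention of multi-predictor screens, but it
is exposed as `min_votes` because published target lists often retain
genes below their stated cut-off. Only the seed region is modelled: no
3'-supplementary pairing, thermodynamic scoring or conservation
filtering. The `6mer-A1` vocabulary entry denotes the A1-anchored
hexamer match; its 7-nt footprint coincides with `7mer-A1` and it does
not participate in the voting modes.

Coordinates are 1-based inclusive on the UTR in 5'-to-3' orientation,
the convention used when designing site mutagenesis primers.

## Evidence combination and ranking

Per-cohort correlation p-values are first made one-sided in the
expected (anticorrelation) direction -- $p/2$ when the observed sign
matches, $1 - p/2$ otherwise, 0.5 for a zero effect -- and then
combined across the cohorts where a correlation is available:

* **Fisher:** $X^2 = -2\sum_i \ln p_i \sim \chi^2_{2k}$ (upper tail).
* **Stouffer:** $Z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ with
  $z_i = \Phi^{-1}(1-p_i)$, equal weights by default.

The "combined correlation p-value" interpretation -- combining the
*correlation* p-values rather than the tumor/normal p-values -- follows
the role of this column as the sort key of the published-style target
table; the combined tumor/normal Fisher p-value is also reported as a
supplementary column. Fisher is the primary sort key with Stouffer as
tie-break (configurable via `sort_key`): Fisher is the more sensitive
of the two to a single very small component, which matches the intent
of ranking by the strongest joint anticorrelation evidence. Both
combiners floor their result at 1e-300 and never print 0; an exact 0
in a published table is treated as numerical underflow, not as a value
to reproduce.

A gene is **ranked** only when it passes all three filters (votes,
deregulation in *every* cohort with `fdr <= fdr_max` and the expected
fold sign, expected correlation sign in every cohort with a defined
correlation); everything else is retained in the report unranked, and
genes passing all filters but lacking any correlation evidence are
flagged `no_correlation` rather than silently dropped.

## Median-effect and combination-index analysis

The median-effect model $f_a/f_u = (D/D_m)^m$ is fit by ordinary least
squares on the linearization
$\log_{10}(f_a/(1-f_a)) = m\,\log_{10} D - m \log_{10} D_m$, the
classical procedure of combination-index software. $D_m$ is the
median-effect dose -- the CC50 when the endpoint is cytotoxicity -- and
$m$ the sigmoidicity. Points with $f_a \in \{0, 1\}$ have an undefined
logit and are excluded with a warning (minimum two interior points).
The CC50's standard error is propagated from the linear fit's residual
variance by the delta method on $-\beta_0/\beta_1$ and is labelled a
standard error explicitly, since published "±" values often leave the
dispersion measure unstated.

The combination index at an observed fraction affected is the
mutually-exclusive (Loewe) form
$\mathrm{CI} = d_1/D_{x1}(f_a) + d_2/D_{x2}(f_a)$ -- the default of
standard combination-index software -- with the non-exclusive variant
(adding $\sqrt{d_1 d_2/(D_{x1}D_{x2})}$) behind `exclusive = FALSE`.
CI < 1 indicates synergy, 1 additivity, > 1 antagonism. CI is invariant
under per-drug dose-unit rescaling, which the tests assert.

## Promoter motif scanning

The PWM scanner scores every window of the region 5' of the ATG on both
strands with $\sum_j \log_2(p_{b_j,j}/q_{b_j})$ and reports windows at
or above the threshold in ATG-relative coordinates (base immediately 5'
of the A of ATG = -1), most-upstream first. The threshold may be given
in log-odds units or as a fraction of the maximum attainable score.
The default matrix expands an E2F-like consensus `TTTSSCGC` with 0.95
probability mass on the consensus base(s) per position. No claim is
made to reproduce any published promoter coordinates: those depend on
the specific genomic sequence build and prediction tool, neither of
which is recoverable; the scanner is the generic primitive such an
analysis needs.

## The synthetic-data module

Because the patient cohorts behind this kind of screen are typically
not deposited, the package ships generators that emulate their
statistical structure with known ground truth:

* **Cohorts** are generated directly on the log2 scale (the pipeline's
  statistics operate on continuous expression; no count model). The
  miRNA is $\mathcal N(\mu + \delta\,\mathrm{tumor}, \sigma)$; planted
  targets follow $\beta_0 + s\,\mathrm{miRNA} + \varepsilon$ so they
  are simultaneously tumor-downregulated (expected fold $s\delta$) and
  anticorrelated. Two decoy classes make the composite filter
  non-trivial: tumor-downshifted genes without miRNA coupling, and
  miRNA-coupled genes without net tumor shift (5% of background genes
  each by default). Noise is Gaussian and homoscedastic. Default study
  conditions: 3 cohorts, 500 genes, 5 planted targets, slope $-1$,
  miRNA shift $+2$, noise s.d. 1, 30 tumor + 30 normal samples, 20
  matched.
* **Matched samples** default to a flagged subset of tumor samples
  (published matched-sample correlations are computed without the set
  ever being defined; within-tumor correlation is the conservative
  reading). A `pooled` mode spanning tumors and normals is also
  provided; with pooled matching the miRNA's tumor shift contributes to
  the correlation, which is how a near-noiseless planted target attains
  $r < -0.99$. Neither mode is asserted to be the published one.
* **UTRs** are random sequences at a configurable GC content with
  planted seed sites; planting rejection-samples until no *unplanned*
  site of equal-or-higher stringency than the weakest planted type
  exists outside the planted intervals, so the scanner's truth set is
  exact.
* **Dose-response series** follow the median-effect model with noise on
  the logit scale; additive combinations place component doses on the
  Loewe line $d_1/D_{x1} + d_2/D_{x2} = 1$ at a fixed dose ratio, so
  the ground-truth CI is exactly 1.

Every generator is a pure function of (config, seed): the global RNG
state is saved and restored around each call, and identical inputs
reproduce byte-identical output.

What passing on these fixtures does **not** show: real expression data
have heavy tails, batch structure, normalization artefacts and
correlated genes; real dose-response data have plate effects and
heteroscedastic error; real 3'-UTRs have compositional structure and
conserved elements. The generators validate the *statistical logic* of
the pipeline, not its robustness to those real-data features.

## Numerical choices and degenerate inputs

* p-value floor 1e-300 throughout; combined p-values and perfect
  correlations are floored, never printed as 0. Stouffer rejects
  boundary inputs (0 or 1) outright, instructing the caller to
  pre-floor, because $\Phi^{-1}$ is infinite there.
* Constant pooled data in the permutation test give $p = 1$ by
  convention; exhaustive ties are counted with a $10^{-12}$ tolerance
  on the statistic comparison.
* Zero variance in a correlation input is an error (undefined), not an
  `NA`, so silent degeneracies cannot propagate.
* Rank ties are broken by the secondary combined p-value and then the
  gene identifier, making the ranking total and deterministic.
* One root seed drives a whole pipeline run; per-cohort seeds are
  derived as `seed + cohort index - 1`, permutation blocks advance the
  seed per block, and every output file header records the seed and a
  config fingerprint, so equal configs yield byte-identical outputs.

## Problem sizes used by the test suite

The suite validates against brute-force oracles (exhaustive window
scanners, enumeration of permutation assignments, the step-up FDR
definition) on hundreds of randomized small cases, and runs the full
synthetic study (500 genes x 3 cohorts) end to end, a 50-replicate
ranking-AUROC study, a 2,000-gene null calibration, and 200-series
median-effect recovery. These sizes were chosen so the complete suite
exercises every claim at meaningful statistical resolution while
remaining comfortable to run locally.

## Known limitations

* The consensus vote emulates prediction-program diversity with seed
  stringency modes; it cannot reproduce any specific external
  predictor's gene list.
* Expression input is assumed normalized, log2-scale, and
  batch-corrected upstream; the package performs no normalization.
* The permutation test assumes exchangeability of samples under the
  null within a cohort.
* The median-effect fit is unweighted least squares on the linearized
  model (the classical procedure); points near $f_a = 0$ or 1 get
  large logit leverage, and no robust or weighted variant is enabled
  by default.
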