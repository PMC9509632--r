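---
title: "chromeq: models and methods"
author: "chromeq maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromeq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromeq)
```

This vignette explains what `chromeq` computes and why the defaults are
set the way they are: the equalized-binarization preprocessing, the
Bernoulli-emission chromatin-state HMM and its state-number selection,
the windowed differential-abundance test, the co-occupancy screen, the
gene-association statistics, and the synthetic-data generator that the
test suite exercises all of them against.

## The problem setting

The package targets two-condition designs: the same panel of chromatin
features (histone variants such as H3.3 or H2A.Z, acetylation marks,
accessibility) profiled genome-wide in a control and a perturbed cell
state, summarized as fixed-width 200-bp bins. Three questions recur:

1. Which combinatorial chromatin states exist, and where do they change
   between conditions?
2. Which individual features gain or lose occupancy, where?
3. Which other DNA-binding factors co-occupy the sites of interest, and
   how do chromatin classes relate to transcriptional change?

## Equalized binarization

Joint two-condition state modeling is exquisitely sensitive to depth and
IP-efficiency differences: the deeper condition simply calls more bins
"present", which a joint model will misread as biology. The equalization
step removes this bias before modeling:

1. `background_subtract()` scales the control track to the signal
   track's total count and subtracts it elementwise, flooring at zero.
   Features without a control (e.g. accessibility) pass through.
2. `poisson_binarize()` calls a bin present when the Poisson upper-tail
   probability of its count, under a background rate taken from the
   scaled control and floored at the genome-wide mean signal, is at most
   `p_threshold` (default `1e-4`, the conventional default of binned
   binarization tools; configurable). The flooring prevents zero-rate
   bins from being called on a single stray read.
3. `equalize_calls()` then ranks, per feature, per chromosome, the
   background-subtracted signal under the present calls of each
   condition and keeps the top *n* calls in both, where *n* is the
   smaller condition's call count. Ties are broken deterministically by
   (signal descending, position ascending). Equalization is per
   chromosome, not genome-wide, so local depth structure cannot shuffle
   calls across chromosomes. Ranking uses whatever values
   `background_subtract()` returned, so features lacking a control are
   ranked on raw signal.

After this step both conditions carry exactly the same number of
present calls per feature per chromosome; all downstream state
differences are differences in *where* the calls sit.

## The chromatin-state model

`fit_hmm()` fits a hidden Markov model over the binarized feature
vectors x_t ∈ {0,1}^F with per-state Bernoulli emissions

P(x | state k) = ∏_f E_kf^{x_f} (1 − E_kf)^{1 − x_f},

a K × K transition matrix and an initial distribution. Every chromosome
of every condition is one independent observation sequence; all
sequences share one parameter set. This "concatenated" design is the
point of the equalization above: states mean the same thing in both
conditions, so decoded paths are directly comparable.

Fitting is plain Baum–Welch EM with a compiled, scaled forward–backward
E-step. Numerical choices:

- **Initialization.** Seeded k-means on the bin vectors (subsampled to
  20,000 rows), centers perturbed by ±0.05 uniform noise and clamped to
  [10⁻³, 1 − 10⁻³]; transitions start at 0.9 self-transition with the
  remainder uniform; the initial distribution is uniform. k-means starts
  are stable and reproducible, and the self-transition boost encodes the
  strong positional persistence of chromatin domains.
- **Restarts.** Three seeded restarts by default, keeping the best
  log-likelihood. Bernoulli-HMM likelihoods are multimodal; restarts are
  cheap insurance. For a fixed seed the fit is bit-reproducible.
- **Clamping.** Emission entries are clamped to [10⁻⁶, 1 − 10⁻⁶] every
  M-step to avoid degenerate likelihoods.
- **Convergence.** EM stops when the absolute log-likelihood change
  falls below `tol * (|loglik| + 1)` with `tol = 1e-6`, or at `max_iter`
  (200). The per-iteration log-likelihood trace is retained and is
  non-decreasing (asserted in the tests).

`decode_states()` assigns each bin its argmax posterior state
(forward–backward), which is deterministic given model and data, and
`state_enrichment()` scores a query interval set against the decoded
path at bin granularity: observed state-k bins overlapped by the query
versus the expectation query_bins × state_bins / total_bins, with an
upper-tail hypergeometric p-value.

## Choosing the number of states

`select_optimal_states()` implements a two-criterion selection against
the most complex model in a fitted series (e.g. K = 5..40 on real data;
the tests use K = 4..12 against a truth of 8):

- `median_max_state_correlation()`: for each state of the reference
  (largest-K) model, the best Pearson correlation of its emission row
  with any candidate state's row, summarized by the median. Constant
  rows correlate as 0 rather than NaN. The statistic is invariant to
  state relabeling in either model.
- `kmeans_goodness()`: k-means (10 seeded restarts) on the pooled
  emission rows of *all* models in the series, with k equal to the
  candidate's state count, returning between-cluster over total
  sum-of-squares. We read "goodness of fit relative to the most complex
  model" as per-candidate k on the pooled rows; the per-candidate k is
  the only reading that makes the criterion a function of the candidate.

The selected K* is the smallest K with both criteria strictly above the
threshold (default 0.95, mirroring the ">95%" convention); if none
qualifies the largest K is returned with a warning. On synthetic series
the goodness criterion is the binding one: over-parameterized models
invent low-occupancy noise states whose emission rows sit far from any
cluster, so the crossing sits at or slightly above the true K — the
same behavior that places the optimum well below the largest fitted
model on real data.

## Differential abundance

`differential_abundance()` tests per-region feature occupancy between
two conditions (n = 2 per condition is the designed case) over a
consensus region set (`build_consensus()`, the flattened union of the
per-condition peak sets):

1. **Abundance filter.** Regions with average log₂CPM < −3 are removed.
   log₂CPM uses prior count 2: `log2((y + 2) / (lib + 4) * 1e6)`;
   a region exactly at −3 is retained.
2. **Loess MA normalization** (`loess_offsets()`). Global efficiency
   differences between IPs are treated as technical, so the null is a
   symmetric MA distribution. For each sample, M = that sample's log₂CPM
   minus the row-mean reference (the log₂ geometric-mean CPM) is
   regressed on A (average log₂CPM) by loess (span 0.4, degree 1); the
   fitted trend is the sample's offset. Offsets are expressed relative
   to the reference, so a 4-fold global scaling of one of two samples
   appears as offsets of about +1 and −1 (difference log₂4 = 2); only
   between-sample differences matter downstream, where offsets adjust
   the effective library sizes on the natural-log scale.
3. **Moderated NB quasi-likelihood test** (`test_differential()`).
   Per-region dispersions are estimated by method of moments from a
   Poisson group fit, smoothed by a loess trend on A, and the trended
   dispersion is used in per-region NB fits (vectorized Newton scoring
   for the group means with offsets; all fits share closed-form score
   and information). The condition effect is tested by F = LR / s²,
   where LR is the likelihood-ratio statistic and s² an
   empirical-Bayes-squeezed quasi-dispersion (deviance/df shrunk toward
   its abundance trend via `limma::squeezeVar`), referred to
   F(1, df_prior + df_resid). The prior df is estimated from the data by
   default; `prior.df` can be fixed by the user, but a fixed small prior
   df misstates the denominator df when the data genuinely share a
   common quasi-dispersion and makes the test conservative, which is why
   estimation is the default. Calibration is the acceptance property:
   on null NB simulations the pooled type-I error at p < 0.05 sits
   inside the 99% binomial interval, and the test tracks an independent
   edgeR QL analysis closely on the same data (cross-checked in the
   suite).
4. **Merging and FDR** (`merge_and_adjust()`). Tested regions are merged
   greedily left-to-right: a neighbor joins the current merged region if
   the gap is ≤ 500 bp *and* the merged width stays ≤ 5 kb (both
   boundaries inclusive; a single wider region passes through). The
   representative p of a merged region is the minimum over members, its
   log₂FC is the minimum-p member's (the representative probability is
   specified; taking the matching member's effect size is our
   convention). BH adjustment runs across merged regions — after
   merging, not before — and direction is the sign of log₂FC at
   FDR < 0.05.

## Co-occupancy screen

`partition_targets()` splits a target site set into marker-positive and
marker-negative classes by ≥1 bp overlap (configurable).
`factor_screen()` then, per catalog factor, cross-classifies target
*sites* (not bp) by factor overlap and class, computing the sample
cross-product odds ratio (Inf on a zero denominator, no Haldane
correction), the two-tailed Fisher exact p, and the fraction of all
target sites overlapped. The screen filters are OR > 2 and overlap
fraction > 0.1%. Site-level units are the default because the overlap
filter is expressed as a percentage of binding sites; a per-bp variant
would weight broad sites more and is deliberately not the default.

## Gene association

`promoter_proximal_genes()` assigns peaks to genes whose
strand-symmetric promoter window [TSS − 3 kb, TSS + 3 kb) they overlap
(half-open right edge; a peak starting exactly at +3 kb is outside).
`geneset_enrichment()` reports the hypergeometric upper tail and the
Fisher odds ratio of a query set against an annotation within a
universe; the hypergeometric p equals the one-sided Fisher p on the
induced table, which the tests assert. `directional_association()`
cross-tabulates up/down direction of genes significant in two DE tables
and applies the uncorrected chi-squared test; `fc_correlation()` reports
Pearson and Spearman correlations of log₂FC over co-detected genes;
`coregulated_genes()` intersects significant, direction-filtered gene
sets across any number of tables. Enhancer classification
(`classify_enhancers()`) labels H3K27ac peaks as super-enhancer
constituents (ATAC + super-enhancer overlap), promoter-proximal
(nearest-edge TSS distance ≤ 3 kb, inclusive — ties favor the promoter
class), typical enhancers (ATAC⁺, > 3 kb from every TSS, outside
super-enhancers), or other.

## The synthetic-data generator

`synthetic_scenario()` fixes the study conditions the tests run under;
the defaults are one deliberate choice of a realistic desk-scale design,
not tuning knobs:

- genome: 3 chromosomes × 1 Mb at 200-bp bins (5,000 bins per
  chromosome, 15,000 per condition) — large enough for stable EM, small
  enough for seconds-scale fits;
- K_true = 8 states over F = 6 features, mean dwell 20 bins
  (4 kb domains, enhancer/promoter scale);
- emissions from `default_emissions()`: one strong (0.9) feature per
  state for the first F states, then distinct feature pairs
  (0.85/0.6) over a 0.05 background — every row distinct and
  recoverable, resembling the one-or-two-mark definitions of real
  chromatin states;
- Poisson depth 10 reads per present bin over background rate 1;
  controls are uniform-background Poisson tracks so that subtraction
  sees realistic noise;
- condition B reuses condition A's state path with 5% of bins switched
  in contiguous geometric blocks of mean 10 bins (2 kb), mimicking
  enhancer-scale remodeling rather than salt-and-pepper flips;
- counts: 2,000 regions (400 bp every 1 kb, so the 600-bp gaps exceed
  the 500-bp merge limit and regions stay distinct), gamma-distributed
  relative abundances, NB dispersion 0.05, library size 10⁶ per sample,
  2 vs 2 design, 10% planted effects at |log₂FC| = 2, half up and half
  down so composition stays balanced under normalization;
- factor catalogs: per-site Bernoulli membership with the negative-class
  rate 0.15–0.2 and the positive-class rate solved from the planted odds
  ratio; factor peaks are the central half of each overlapped site.

All generators are pure functions of (scenario, seed). What the
generator does **not** emulate: replicate batch effects, GC and
mappability bias, fragment-length effects, correlated features beyond
the state structure, and peak-calling noise (region sets are exact).
Passing tests therefore demonstrate the statistics are implemented
correctly and calibrated under their own assumptions — not that those
assumptions hold on any particular real dataset.

## Problem sizes and determinism

The test suite and the acceptance script run, per invocation: one
15,000-bin-per-condition HMM recovery fit; ten replicate series of nine
fits each (K = 4..12) on 7,500-bin-per-condition data for state-number
selection; twenty null and ten planted 2,000-region differential
simulations; one hundred screen replicates at 5,000 sites; and
exhaustive 2×2-table checks up to total 40. These sizes keep a full run
in minutes on one core while leaving the Monte-Carlo intervals tight
enough to be meaningful. Every stochastic step takes an explicit integer
seed, and file outputs round-trip bit-exactly through the plain-text
readers and writers (BED, bedGraph, chrom.sizes, model JSON, binarized
calls, segment BED, counts TSV).

## Known limitations

- The HMM trainer is a faithful Baum–Welch implementation, not a clone
  of any external segmentation tool; with a different initialization
  heuristic, state *identities* may differ from other tools even when
  the emission structure is equivalent (state matching by correlation is
  the supported comparison).
- The differential test supports the two-condition design only; no
  covariates, no multi-factor designs.
- The moderated QL test is a documented simplification validated by its
  simulation properties (calibration, power, sign accuracy, agreement
  with an independent reference pipeline), not numeric identity with any
  specific package.
- `naive_overlap_peakset()` measures coverage of the pooled peak by the
  union of each replicate's peaks; reciprocal single-peak overlap is a
  different (stricter) rule and is not implemented.
- Peak–peak overlap defaults to ≥1 bp wherever a fraction is not
  specified; the threshold is configurable at the call sites that use it.
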