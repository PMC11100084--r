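---
title: "screenperm: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{screenperm: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

A low-MOI single-cell CRISPR screen delivers one guide RNA (gRNA) per
cell — either targeting a genomic element or non-targeting (NT) — and
reads out a gene-by-cell UMI count matrix. For a perturbation–gene
pair, the cells carrying the perturbation are the *treatment* group and
(by default) the NT cells are the *control* group. We model the
response count of cell $i$ as

$$Y_i \sim \mathrm{NB}_\theta(\mu_i), \qquad
  \log \mu_i = \gamma X_i + \beta^\top Z_i,$$

where $X_i$ is the perturbation indicator, $Z_i$ the vector of
technical covariates (always including an intercept; numeric factors
such as library size enter on the log scale), and $\theta$ the NB size
parameter ($\mathrm{Var} = \mu + \mu^2/\theta$; $\theta \to \infty$ is
Poisson). The test of $H_0{:}\ \gamma = 0$ uses the GLM score
statistic, which depends only on the *null* fit of $Y$ on $Z$:

$$z = \frac{X^\top W M(Y-\hat\mu)}
  {\sqrt{X^\top W X - X^\top W Z (Z^\top W Z)^{-1} Z^\top W X}},$$

with weights $W = \mathrm{diag}\{\hat\mu_i/(1+\hat\mu_i/\hat\theta)\}$
and working residuals $M(Y-\hat\mu)_i = Y_i/\hat\mu_i - 1$. Rather than
referring $z$ to its Gaussian limit — unreliable when few treatment
cells express the gene — we permute the treatment labels and compare
the observed $z$ to the permutation distribution of $z$.

**Why this survives the three data pathologies.** The permutation
p-value is finite-sample valid whenever treatment labels are
exchangeable (no confounding), *regardless* of how badly the NB model
fits; and when the mean model is correct up to $\theta$, the
covariate-adjusted statistic removes the confounding signal, so
validity also holds under confounding. Sparsity is handled because no
Gaussian approximation is needed at small effective sample size. The
confounding simulation study (`simulate_camp_study()` /
`run_camp_evaluation()`) exhibits exactly this contrast against a
plain-sum permutation test (breaks under confounding) and parametric NB
regression (breaks under a misspecified $\theta$).

# Algorithmic structure

1. **Null fit** (`fit_null_glm`): IRLS with log link; for estimated
   $\theta$, IRLS sweeps alternate with Newton steps on $\log\theta$
   for the profile NB size likelihood (the literature does not fix an
   estimator; profile ML is the natural choice and is what the
   parameter-recovery tests certify). $\theta$ is clamped to
   $[0.01, 1000]$; at the upper clamp the fit is flagged effectively
   Poisson. Non-convergent NB fits fall back to Poisson with a flag —
   permutation validity is insensitive to $\theta$ when treatment is
   exchangeable, so a conservative family is safer than a failed fit.
2. **Score precompute** (`precompute_score`): the symmetric
   eigendecomposition $Z^\top W Z = Q\Lambda Q^\top$ gives
   $S = \Lambda^{-1/2}Q^\top$ with $S^\top S = (Z^\top W Z)^{-1}$, so
   for a treatment index set $T$,
   $z = \sum_{T} a_i \big/ \sqrt{\sum_T w_i - \lVert S\sum_T d_i\rVert^2}$
   with $a = w \circ$ working residual and $d_i = w_i Z_i$ — $O(|T|q)$
   per resample, evaluated for whole resample banks in a C++ kernel.
   Dense-solve and QR reference paths exist solely as oracles; the
   three agree to $10^{-8}$ relative error by test.
3. **Resampling** (`resample_bank`): one uniformly random ordering of
   the pair's cell universe per resample index; the first $t$ entries
   are a uniform without-replacement draw of any size $t$, so one bank
   serves every pair sharing a universe (inductive without-replacement
   sampling). Orderings are pure functions of (seed, universe key,
   resample index) — batch results are independent of pair order and
   worker count.
4. **Adaptive testing** (`adaptive_config`): stage 1 computes an
   empirical p from $B_1 = 500$ resamples; pairs with $p > 0.01$ stop
   (most truly null pairs do). Promoted pairs get $B_2 = 5000$ fresh
   resamples (indices $B_1{+}1,\dots,B_1{+}B_2$; stage-2 p uses only
   those, not pooled).
5. **Skew-normal tails** (`fit_mom`, `tail_p`): the permutation null is
   asymptotically Gaussian but skewed at finite ESS, so a skew-normal
   is fitted by closed-form moment inversion and the p-value is its
   tail probability — this is what produces p-values far below
   $1/(B+1)$ from only thousands of resamples. Guards: sample skewness
   at/beyond the attainable bound ($\approx 0.9953$) is clamped and the
   fit marked unusable; a one-sample KS distance above 0.05 likewise
   rejects the fit; either way the empirical p-value is returned
   instead. The CDF is evaluated through Owen's T function
   (Boost.Math), with the survival form $\Phi(-u) + 2T(u,\alpha)$ used
   in the heavy tail to avoid cancellation.

# Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `min_gene_frac` | 0.005 | fraction of cells in which a gene must be expressed |
| `min_cells_per_grna` | 10 | cells per retained gRNA |
| `ess_min` | 7 | cells with perturbation *and* nonzero expression |
| `B1`, `B2` | 500, 5000 | stage-1 / stage-2 resample counts |
| `p_thresh` | 0.01 | stage-1 promotion threshold |
| `gof` threshold | 0.05 | KS distance ceiling for the skew-normal fit |
| `theta` clamp | [0.01, 1000] | NB size bounds; upper clamp = Poisson-like |
| `bonferroni_level` | 0.1 | family-wise level of the calibration check |

The QC defaults and `ess_min = 7` reproduce the benchmarking protocol
this package implements; the ESS threshold marks where both calibration
and power of the score-permutation test degrade.

# Synthetic data: what it emulates and what it does not

`simulate_null_screen()` draws gene-wise NB means from Gamma(shape 0.5,
rate 2) — mean 0.25 UMI/cell, i.e. mostly lowly expressed genes — and
sizes from Unif(1, 25); every cell gets one NT gRNA uniformly at random
(multinomial, equal expected cells per gRNA; the alternative fixed
count-per-gRNA scheme would differ only in $O(\sqrt{n})$ group-size
noise). The Gamma is read as shape/rate, the convention of the
statistical environment the generators emulate. Every pair is truly
null, so a green calibration check certifies type-I error control
under sparsity — but *not* under confounding (no technical structure is
generated) nor under real-data departures from NB (zero inflation,
ambient RNA, cell-cycle structure). The positive-control generator
links each PC gRNA to one distinct gene (the linkage is emitted as a
truth table) and redraws that gene's mean independently in the gRNA's
cells, giving effects of random, occasionally negligible, magnitude —
power assertions therefore compare linked against unlinked pairs rather
than demanding every linked pair be detected.

`simulate_camp_study()` emulates a single confounded pair: a two-level
batch shifts the log-mean by $\pm 0.75$ and (in the confounded arms)
tilts the assignment probability (0.02 vs 0.08, marginal 0.05);
$\theta^* = 4$; the misspecified arms hand the methods $5\theta^*$.
With these stated parameters the analytic variance inflation of the
parametric NB z-statistic is only $\approx 1.2$ (the weight ratio
$(1+\mu/\theta^*)/(1+\mu/5\theta^*)$ at $\mu \approx 0.7$), which a
rejection-rate comparison at 500 replicates cannot resolve reliably;
the acceptance suite therefore measures the inflation as the paired
second-moment ratio of z between the misspecified and correct arms
(same response draws, so the ratio is nearly noise-free) against a
threshold of 1.1, midway between the null value 1 and the
analytic/pilot value.

# Numerical choices and edge cases

- Empirical p-values use the add-one convention $(1 + \#\{z_b \ge
  z\})/(B+1)$, guaranteeing validity; two-sided p is $\min(1,
  2\min(p_L, p_R))$ on both the empirical and skew-normal paths.
- Fold change: $\log_2$ ratio of library-size-normalized mean
  expression, treatment over control, with a 0.5-UMI pseudocount
  (0.5/mean library size on the normalized scale) so zero-mean groups
  stay finite.
- Degenerate pairs (all-zero response in the universe, nonpositive
  score variance) are flagged `qc_pass = FALSE` with p = 1; a batch
  never aborts.
- Derived library size is floored at 1 UMI before the log transform;
  relevant only for tiny fixtures where a cell can have an empty
  transcriptome.
- Filter order in dataset QC is cells → genes → gRNAs, so the gene
  expression fraction refers to retained cells (the protocol lists the
  filters unordered; this reading makes the fraction well defined).
- Wilcoxon diagnostic uses mid-ranks with the standard tie-corrected
  variance; relative expression uses the natural log.
- Equal-frequency ESS binning assigns by rank (sizes within one of
  each other even under ties); explicit bins are disjoint integer
  intervals.
- Negative-control matching subsamples candidates uniformly without
  replacement under a derived seed; NT grouping (when the discovery
  analysis is grouped) randomly partitions NT gRNAs into groups sized
  like the discovery groups.

# Known limitations

- No zero-inflated or quasi-likelihood families; the model is plain NB
  (with Poisson as a limit), as in the protocol implemented.
- gRNA-to-cell assignment is taken as given; no assignment from gRNA
  count matrices, doublet detection, or mitochondrial-content QC.
- The high-MOI setting (multiple perturbations per cell, conditional
  randomization inference) is out of scope.
- `run_batch()` parallelism forks per response group; with very few
  genes the speedup is limited.
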