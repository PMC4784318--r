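---
title: "Models and methods behind sortseqtools"
author: "sortseqtools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sortseqtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortseqtools)
```

## The measurement model

Sort-seq couples fluorescence-activated cell sorting with deep sequencing:
a library of genetic variants is sorted into $m$ fluorescence gates and
each gate is sequenced, so for every variant one observes how its cells
distribute across gates. `sortseqtools` models the per-variant input
distribution of single-cell fluorescence $X$ as log-normal,

$$F_{\mu,\sigma}(x) = \tfrac12\left(1 +
  \mathrm{erf}\!\left(\frac{\log x - \mu}{\sigma\sqrt2}\right)\right),$$

with linear-scale mean $\nu = e^{\mu + \sigma^2/2}$ and coefficient of
variation $c = \sqrt{e^{\sigma^2} - 1}$ (`moments_to_params()` /
`params_to_moments()`; $c \approx \sigma$ for small widths). Gates are
log-spaced intervals $[L_j, U_j)$ of common log-width $w$
(`make_log_gates()`); *semibounded* configurations extend the outermost
gates to $0$ and $\infty$, which we represent with exact sentinels so the
gate probabilities $p_j = F(U_j) - F(L_j)$ partition the support exactly.
Simulation (`sample_output()`) draws cells by inverse-CDF sampling and
bins them; in bounded configurations cells outside $[\ell, u]$ are drawn
but never sorted, and this distinction — cells drawn versus cells sorted —
is deliberate: it is what produces the boundary bias of naive estimators.
We kept "drawn" as the budget definition (a flag through `bin_cells()`
output accounting lets users reason about both).

## Estimators

* **Simple estimators** (`simple_mean()`, `simple_cv()`) place every cell
  of gate $j$ at $\varphi_j = b\sqrt{L_j U_j}$ with
  $b = w/(e^{w/2} - e^{-w/2})$, the constant that minimizes mid-range
  bias. They are cheap and unbiased when the input width is comparable to
  the gate width ($\sigma \gtrsim w$), oscillate with $\nu$ when
  $\sigma \ll w$ (gate quantization), overestimate the CV for narrow
  inputs, and are badly biased within a factor $e^{2\sigma}$ of the
  measurement boundaries because the out-of-range tail is invisible.
* **Binned MLE** (`mle_fit()`) maximizes
  $\sum_j r_j \log\left(F(U_j) - F(L_j)\right)$ with Nelder-Mead on
  $(\mu, \log\sigma)$; log-parameterizing $\sigma$ keeps it positive
  without constraints. Semibounded gates enter as censored terms, which
  removes the boundary bias. Convergence tolerances are $10^{-8}$
  relative with at most $10^4$ iterations and one simplex restart from
  the optimum; initialization is moment-based from the occupied gates.
  These are our choices — the source recipe specifies the simplex method
  but not its controls.
* **Robust censored MLE** (`robust_mle_fit()`) models a fraction
  $\gamma$ (default 5 %) of mis-sorted/mis-identified cells distributed
  like the global per-gate fractions $T_j$:
  $\lambda_j = (1-\gamma)p_j + \gamma T_j$. The extreme gates are always
  treated as censoring gates. Goodness of fit is the KL divergence
  between observed and fitted fractions in bits, and the QC filter
  applies, in order, a 300-read floor, concentration rules (> 60 % in one
  gate, > 90 % in the top two, > 40 % in a censoring gate), and a 0.4-bit
  divergence ceiling. For the two-gate rule we take the top two gates *by
  count*, adjacent or not.
* **Reference estimator** (`reference_estimate()`): the log-sample MLE
  from raw fluorescence values; `run_benchmark()` feeds it the same draws
  that were binned, making efficiency $\eta = \mathrm{MSE}_{\rm
  ref}/\mathrm{MSE}_{\rm sortseq}$ a paired comparison with much lower
  Monte Carlo noise. Benchmarks center the gate range so the $\nu$-grid
  midpoint falls on the middle gate boundary; the absolute placement is
  otherwise arbitrary.

## Regrouping, enrichment, and depth normalization

`regroup_gates()` merges adjacent gates (fractions and totals add;
boundaries span the union), emulating coarser designs from fine-grained
data. For read-count tables, per-gate depth factors
$d_j = h_j/\sum_i r_{ij}$ convert reads to estimated sorted cells
*before* merging — depth is a per-original-gate sequencing artifact, so
this order matters and is fixed here. Enrichment
(`enrichment_below()`, `expected_enrichment()`) is the fraction of a
variant's cells on one side of a threshold; analytically
$\varepsilon = 1 - F_{\mu,\sigma}(\tau)$, a sigmoid in $\mu$ whose
dynamic range widens with $\sigma$.

## Sequence-activity models

`activity_model()` holds an additive model
$G(Q) = G_0 + \sum_p H_{p,Q_p}$ with the reference base gauge-fixed to
$H = 0$, plus optional pairwise interactions $J$ (symmetric, reference
entries zero, each unordered pair counted once). Random model draws
follow the robustness parameterization: $H \sim \mathcal N(-G_0/R,
(4G_0/3R)^2)$ so that after $R$ random mutations the expected activity
crosses zero, and $J \sim \mathcal N(0, (SG_0/R)^2)$ with interaction
power $S$. Activity maps to mean fluorescence through either the
two-state repression form $\nu = \nu_{\rm null}(1+e^G)^{-1}$ or the
expression form $\nu = 1 + e^G$ (`activity_to_mean()`).

## Model inference

Two fitting routes are implemented and cross-validated against each
other:

* **Nonlinear least squares** (`lsq_fit_additive()`): pushes $G$ through
  the chosen map and minimizes squared differences to per-variant
  estimates via Levenberg-Marquardt with an analytic Jacobian. Three
  losses are available. The `"absolute"` default matches the classical
  recipe ($\sum_i(\hat\nu_i - \nu_i)^2$). Because per-cell noise is
  multiplicative (constant CV), that loss overweights bright variants;
  `"relative"` ($\sum_i(\hat\nu_i/\nu_i - 1)^2$) and `"log"`
  ($\sum_i(\log\hat\nu_i - \log\nu_i)^2$, the log-normal maximum
  likelihood) are provided for heteroscedasticity-aware fits. On the
  library-design instance below the absolute loss pays roughly a
  1.7-fold penalty in parameter RMS error relative to the log loss.
* **Mutual-information maximization** (`mi_of_model()`,
  `mi_fit_montecarlo()`): reads are ranked by model activity, the
  read-by-gate indicator table is compressed in blocks of 1000 rows,
  smoothed along the rank axis by a discrete Gaussian kernel whose sd is
  1 % of the compressed row count, and the MI of the resulting joint
  distribution is maximized by a Metropolis-like search (perturb one
  $H_{p,q}$ by $\mathcal N(0,1)$; keep unless MI drops, in which case
  keep with probability $2^{-n\delta}$). Only the *ranking* of $G$
  enters, so MI is invariant to monotone transforms of $G$ — in
  particular to overall scaling and sign. We fix the scale by dividing
  the free entries by their standard deviation after each kept step (any
  scale rule is rank-equivalent; ensemble averages may differ from other
  rules by a global factor), break ranking ties with a seeded random
  tie-break so constant models score $\approx 0$ bits, renormalize the
  smoothed table to sum exactly to 1 (the truncated kernel otherwise
  loses a little mass at the rank edges), and orient the ensemble-average
  sign so activity correlates positively with gate index. With $n$ in the
  tens of thousands the acceptance rule is effectively zero-temperature,
  and from random starts the search can stall in local optima; the
  default initialization is therefore a moment seed (mean gate index of
  reads carrying each base, relative to the reference base), which the
  Monte Carlo then refines — with it, every instance we tested converged
  to the planted model without temperature exchange, which we omit.
  Random and user-supplied starts remain available. The remainder block
  when 1000 does not divide $n$ keeps its own (smaller) mass.

`information_footprint()` gives the per-position MI between base identity
and gate index — the model-free screen for functionally sensitive
positions.

## The library-design experiment

`run_design_experiment()` compares, under a matched cell budget
($151 \times 20 \approx 3000 \times 1$), direct measurement of all single
mutants (targeted; simple mean of 20 cells each) against model-based
inference from a random library ($3000$ variants, $r_{\rm mut}$ mean
mutations, one cell each) fitted additively. Data are generated with
input CV 0.5 through the expression map into 24 gates of width
$w = 0.3$ covering $[1, 1+e^{\max G}]$ with two-log-sd margins (dead
variants sit at $\nu = 1$, so the lower edge matters). The random-library
fit uses the `"log"` loss with the known-CV mean-median correction
$e^{\sigma^2/2}$ applied to the single-cell estimates: single cells are
median-unbiased on the log scale, and without the correction the fit
inherits a global $-\sigma^2/2$ activity bias that masks the design
contrast. Reported error is the RMS over single mutants of
$(\hat\nu - \nu)/\nu$; both across-repeat means and per-repeat values are
returned. Twenty independent model draws per condition is the default;
the acceptance suite uses eight, which reproduces the three regimes
(random wins for $r_{\rm mut} < R$; reversal for $r_{\rm mut} > R$;
advantage erased at $S \ge 1$) stably across seeds.

## Epistasis statistics

For fold-changes $f$ under the two-state repression map, the additive
null predicts the double mutant as $f_{\rm pred} = C/(C+AB)$ with
$C = f_{WT}^{-1}-1$ etc., and the interaction strength is
$IS = f_{\rm pred}/f_{\alpha\beta}$ ($IS = 1$ exactly under additivity).
The model-free companion is
$K = \log(\varepsilon_{\alpha\beta}\varepsilon_{WT}/
\varepsilon_\alpha\varepsilon_\beta)$ over single-gate enrichments
(natural log by default, configurable). $K$'s null is exact only for
multiplicative enrichments; on two-state data it holds approximately in
the mid-range regime and drifts when enrichments saturate, which is why
$K$ is a screen and $IS$ the quantitative statistic.

## What the synthetic data does and does not emulate

`generate_fixture_library()` and the simulators reproduce multinomial
sampling noise, censoring at the extreme gates, sequencing-depth
imbalance (via $h_j$), and outlier contamination — the features the
estimators are designed against. They do not emulate instrument-level
FACS artifacts (doublets, spectral spillover), PCR amplification bias,
or non-log-normal input families; passing tests therefore validate the
inference machinery under its stated model, not those orthogonal error
modes.

## Problem sizes and numerical choices

The test and acceptance suites run desk-scale versions of each analysis:
estimator benchmarks at $N = 100$ cells and 1000 repeats on 6 gates of
$w = 0.8$; regrouping on a 200-variant, 32-gate synthetic library at
5000 reads/variant; model fitting at $P = 20$, $5\times10^4$ reads with
20,000–60,000 Monte Carlo steps; design comparisons with 8 model draws.
These sizes were chosen so each suite completes in minutes while leaving
the Monte Carlo error well below the tested effect sizes. Degenerate
inputs are handled explicitly: all-in-one-gate counts return
`converged = FALSE` from the bounded MLE, zero-count gates contribute
$0\log 0 := 0$ to likelihoods, zero-read gates with recorded cells get
`NA` depth factors with a warning, and $f_{WT} = 1$ makes the epistasis
prediction degenerate (flagged).

## Known limitations

Single log-normal inputs only (no mixtures); pairwise epistasis at most;
the MI fit estimates additive terms only; enrichment-based $K$ has no
calibrated significance threshold — none is established for these
statistics — and the robust-MLE contamination fraction is a fixed design
constant, not estimated per variant.
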