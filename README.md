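# sortseqtools

Simulation and inference for **sort-seq** (FACS-seq) experiments, in
which a library of genetic variants is sorted into fluorescence gates
and each gate is deep-sequenced. From the resulting binned data one
wants, per variant, the mean expression and the cell-to-cell
variability — and, at the library scale, quantitative sequence-activity
models. The package is aimed at people designing such experiments
(how many gates? how wide? censoring gates or not? one reporter or
two? targeted or random mutant libraries?) and at people reanalyzing
published gate-fraction or read-count tables.

## What it implements

**Measurement model.** Per-variant single-cell fluorescence is
log-normal, `F(x) = ½(1 + erf((log x − μ)/(σ√2)))`, with mean
`ν = exp(μ + σ²/2)` and CV `c = √(exp(σ²) − 1)`. Gates are log-spaced
intervals `[L_j, U_j)` of width `w`, optionally semibounded (censoring)
at the extremes. Simulators cover single-reporter and dual-reporter
(shared × intrinsic noise factor) designs.

**Estimators** for `(ν, c)` from gate counts `r`:

- *simple*: cells placed at gate centers `φ_j = b√(L_j U_j)`,
  `b = w/(e^{w/2} − e^{−w/2})`;
- *MLE*: maximize `Σ_j r_j log(F(U_j) − F(L_j))` (censored terms for
  semibounded gates) by Nelder-Mead;
- *robust MLE*: adds an outlier fraction `γ` spread like the global gate
  occupancy, `λ_j = (1−γ)p_j + γT_j`, plus the read-depth/concentration/
  KL-divergence QC filter;
- *reference*: log-sample MLE from raw values, the yardstick for
  efficiency `η = MSE_ref / MSE_sortseq`.

**Benchmarks** (`run_benchmark`) map estimator bias, MSE and efficiency
over `(ν, σ)` grids; **regrouping** utilities merge gates, normalize
read depth (`d_j = h_j/Σ_i r_ij`), and compute enrichment fractions and
fold-changes. **Sequence-activity models** `G = G₀ + Σ H[p, Q_p] (+ J
pairs)` are fitted by nonlinear least squares through two-state maps or
by mutual-information maximization over ranked reads; **epistasis**
statistics `IS` (additive-null prediction over measured double-mutant
fold-change) and `K` (log enrichment cross-ratio) quantify pairwise
interactions; and `run_design_experiment` compares targeted vs random
library designs end to end.

## Worked example

Simulate one variant (true mean 2, CV 0.6) sorted at 500 cells into 8
semibounded log-spaced gates, then recover the parameters by censored
maximum likelihood:

```r
library(sortseqtools)
set.seed(42)
gates <- make_log_gates(8, 0.25, exp(8 * 0.5) * 0.25, semibounded = TRUE)
pars  <- moments_to_params(nu = 2, c = 0.6)
out   <- sample_output(pars["mu"], pars["sigma"], gates, n_cells = 500)
out
#> <output_counts> 500/500 cells sorted over 8 gates
#> [1]   7  16 100 169 132  65  11   0
mle_fit(out, gates)
#> <estimate_record:mle> nu_hat = 1.9447, c_hat = 0.6137 (mu = 0.50529, sigma = 0.56537, converged = TRUE)
```

The counts are the variant's output distribution — 500 of 500 drawn
cells were sorted because semibounded gates capture both tails. The MLE
recovers the true mean within 3 % and the CV within 2 % from 8 numbers;
`run_benchmark()` shows this is no accident (near-unbiased with
efficiency ≈ 0.9 for `σ ≥ w`), while the simple estimators drift once
`σ < w/2` or the mean approaches a measurement boundary.

See `vignettes/sortseq-methods.Rmd` for the full model and the
reasoning behind each numerical choice.

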