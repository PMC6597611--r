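# ultradyn

Tools for quantifying ultradian (2–5 h period) dynamics of transcription
factor expression in single cells, built around the HES5 autorepression
circuit of neural progenitors. Fluorescent-reporter traces from tissue are
short (~45 points at 15-min sampling), noisy, and ride on slow developmental
trends, so deciding whether a given cell is genuinely *oscillating* — and
what that implies about the gene circuit generating the dynamics — is a
statistical problem, not an eyeballing one.

The package provides:

- **A Gaussian-process oscillation test.** Detrended traces are compared
  under two nested covariance models, an aperiodic Ornstein–Uhlenbeck null
  `K(τ) = σ e^{-ατ}` and a damped-cosine alternative
  `K(τ) = σ e^{-ατ} cos(βτ)`, with the technical-noise variance calibrated
  globally by joint likelihood. Cells are scored by the length-normalised
  log-likelihood ratio `LLR = (2·LL_OUosc − 2·LL_OU)/n` and classified
  against a synthetic null (generated from each cell's fitted OU model and
  re-run through the identical pipeline) at a 3% false discovery rate.
- **A mechanistic stochastic model.** Delayed chemical Langevin equations
  for transcriptional autorepression with Hill function
  `G(P) = 1/(1+(P/P₀)^n)` and transcriptional delay τ, plus the
  deterministic delay-differential limit, the exact steady state, a
  closed-form Hopf bifurcation test, and the analytic linear-noise power
  spectrum of protein fluctuations.
- **Rejection ABC** over biophysically bounded priors, accepting parameter
  samples whose mean expression and relative SD match experiment, with
  posterior predictions of periods, expression variability, coherence
  response to degradation rates, and oscillation-induction likelihoods of
  ±50% parameter changes.
- **Hilbert analytics**: instantaneous amplitude/phase, peak-to-trough fold
  changes on the trend-restored signal, amplitude-death summaries.
- **Dynamics clustering** (Ward/Euclidean on z-scored traces), COV-over-window
  and shoulder-point trend summaries, and imaging-depth correction.
- **FCS-anchored absolute quantification**: two-component diffusion + triplet
  autocorrelation fits, molecule/concentration conversion, and
  quantile–quantile calibration of intensity images to concentration maps.
- **Synthetic-data generators** for every fixture the above need, so the
  whole pipeline is testable without any external data.

## Worked example

Detect oscillators in a synthetic population of ten aperiodic (OU) and ten
oscillatory (3-h damped-cosine) cells, 11 h at 15-min sampling with 10%
technical noise:

```r
library(ultradyn)
set.seed(7)
times <- seq(0, 660, by = 15)
Y <- cbind(
  sapply(1:10, function(i) add_technical_noise(
    100 + gen_gp_trace("OU", 64, 1/100, times = times), 0.8)),
  sapply(1:10, function(i) add_technical_noise(
    100 + gen_gp_trace("OUosc", 64, 1/300, 2*pi/180, times = times), 0.8)))
calls <- classify_oscillators(Y, times)
head(subset(calls, select = -p_value), 4)
#>    cell_id    llr q_value oscillatory period_h sigma_n
#> 1 cell_001 0.3514  0.0227        TRUE     3.55     1.9
#> 2 cell_002 0.1248  0.5237       FALSE     1.75     1.9
#> 3 cell_003 0.0832  0.5810       FALSE     4.17     1.9
#> 4 cell_004 0.2887  0.0998       FALSE     2.53     1.9
which(calls$oscillatory)
#>  [1]  1 11 12 13 14 15 16 17 18 19 20
```

All ten planted oscillators are recovered with fitted periods near 3 h
(`period_h` is `2π/β` from the alternative-model fit; `sigma_n` is the one
globally calibrated noise variance shared by every cell). One OU cell
(`cell_001`) is also flagged: its particular realisation is genuinely
rhythmic-looking, and the 3% FDR bounds exactly how often such calls occur.

On the mechanistic side, simulate an ensemble at an oscillatory parameter
point and summarise its spectrum:

```r
p <- model_parameters(alpha_m = 44.9, alpha_p = 3.13, P0 = 35080.2,
                      hill_n = 5.62, tau = 40)
sim <- simulate_cle(p, simulation_config(n_traces = 200))
ch <- coherence(ensemble_power_spectrum(sim$protein))
#> coherence 0.76 at a 4.3-h spectral period; deterministic Hopf: TRUE
```

A coherence of 0.76 means three quarters of the spectral power sits in a
20% band around the dominant peak — strongly rhythmic dynamics with a
~4.3-h period.

See the vignette (`vignettes/ultradian-dynamics.Rmd`) for the statistical
models, the inference machinery, and every numerical choice.

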