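# shared fixtures: all synthetic, built in code at test time

std_times <- function(n = 45L, by = 15) seq(0, by = by, length.out = n)

# a batch of OU or OUosc traces with additive technical noise
noisy_gp_traces <- function(n_cells, times, kind = "OU", variance = 1,
                            lengthscale = 1 / 100, period_min = 180,
                            noise_frac = 0.1) {
  beta <- if (kind == "OUosc") 2 * pi / period_min else 0
  vapply(seq_len(n_cells), function(i)
    add_technical_noise(
      gen_gp_trace(kind, variance, lengthscale, beta, times),
      noise_frac * sqrt(variance)),
    numeric(length(times)))
}

oscillatory_point <- function() model_parameters(
  alpha_m = 44.9, alpha_p = 3.13, P0 = 35080.2, hill_n = 5.62, tau = 40)

aperiodic_point <- function() model_parameters(
  alpha_m = 0.64, alpha_p = 17.32, P0 = 88288.6, hill_n = 5.59, tau = 34)

# one shared desk-scale posterior for the acceptance checks (computed once)
.fixture_cache <- new.env(parent = emptyenv())

acceptance_posterior <- function() {
  if (is.null(.fixture_cache$post)) {
    set.seed(101)
    .fixture_cache$post <- abc_reject(sample_prior(20000), backend = "lna")
  }
  .fixture_cache$post
}
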