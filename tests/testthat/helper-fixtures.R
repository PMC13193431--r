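# shared fixtures built in code

# two-fish read set used in the worked precision examples
reads_toy <- data.frame(read1 = c(2, 5), read2 = c(3, 5))

# monthly edge table drawn from a given periodicity truth
make_edge_table <- function(seed, hypothesis = "one_peak",
                            params = c(mu = 2 * pi * 11.5 / 12, kappa = 2,
                                       A = 0.9),
                            n_m = 30) {
  set.seed(seed)
  pim <- edge_probability(1:12, list(hypothesis = hypothesis,
                                     params = params))
  data.frame(month = 1:12, n = n_m, k = stats::rbinom(12, n_m, pim))
}

# small noise-free population: single sampling month at the deposition
# peak, so capture sizes sit exactly on the growth curve
noisefree_config <- function(n_fish = 30, seed = 7) {
  sim_config(n_fish = n_fish, growth_sd = 0, vr_sd = 0,
             read_error_prob = 0, selectivity = NULL,
             sampling_months = data.frame(year = 2022, month = 12),
             seed = seed)
}

logistic_truth_m <- list(linf = 401.70, k = 0.45, t0 = -0.36)
logistic_truth_f <- list(linf = 512.22, k = 0.29, t0 = 0.82)

# reduced MCMC settings for tests; the package default run is larger
fit_small <- function(obs, family, seed = 1, warmup = 300, iter = 600, ...) {
  suppressWarnings(growth_fit(dw ~ age, obs, family = family,
                              chains = 2, warmup = warmup, iter = iter,
                              adapt = 300, seed = seed, ...))
}
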