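# Shared fixtures: the unit-mean interdivision-time test matrix and small
# numeric utilities used across test files.

unit_mean_models <- function() {
  list(
    exponential = interdivision_model("exponential", mean = 1),
    deterministic = interdivision_model("deterministic", mean = 1),
    gamma_05 = interdivision_model("gamma", mean = 1, shape = 0.5),
    gamma_2 = interdivision_model("gamma", mean = 1, shape = 2),
    gamma_4 = interdivision_model("gamma", mean = 1, shape = 4),
    lognormal_025 = interdivision_model("lognormal", mean = 1, cv = 0.25),
    lognormal_05 = interdivision_model("lognormal", mean = 1, cv = 0.5),
    lognormal_1 = interdivision_model("lognormal", mean = 1, cv = 1))
}

# CDF of a density tabulated on a fine grid (trapezoid cumsum), for
# Kolmogorov-Smirnov comparisons of simulated samples against the analytic
# age distributions.
cdf_from_density <- function(dens, tmax, n = 4000L) {
  g <- seq(0, tmax, length.out = n + 1L)
  f <- dens(g)
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(g)))
  cum <- pmin(cum / max(cum), 1)
  stats::approxfun(g, cum, yleft = 0, yright = 1)
}

ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  u <- cdf(x)
  max(abs(u - seq_len(n) / n), abs(u - (seq_len(n) - 1) / n))
}

rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-12))
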