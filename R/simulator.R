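fam_code <- function(model) {
  switch(model$family,
    exponential = list(code = 0L, p1 = model$mean, p2 = 0),
    gamma = list(code = 1L, p1 = model$shape, p2 = 1 / model$rate),
    lognormal = list(code = 2L, p1 = model$meanlog, p2 = model$sdlog),
    deterministic = list(code = 3L, p1 = model$mean, p2 = 0),
    stop("the simulator supports exponential, gamma, lognormal and ",
         "deterministic interdivision laws (not `custom`)"))
}

default_x0 <- function(net, model) {
  ps <- population_structure(model)
  round(init_birth_state(net, ps)$mean * 2) # deterministic steady state
}

#' Exact stochastic simulation of a cell's chemistry
#'
#' Runs the direct stochastic simulation algorithm for the reaction network
#' over a time interval within one cell (no divisions). Burst-production
#' reactions fire at their base rate and add a geometric number of
#' molecules per firing.
#'
#' @param net A [reaction_network()].
#' @param counts Named or ordered integer state vector.
#' @param duration Simulated time (>= 0).
#' @param seed Optional integer seed.
#' @return Integer counts at the end of the interval.
#' @export
ssa_within_cell <- function(net, counts, duration, seed = NULL) {
  stopifnot(duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  x <- as.integer(as_state(net, counts))
  if (any(x < 0)) stop("counts must be nonnegative")
  out <- ssa_cpp(net_to_cpp(net), x, duration)
  stats::setNames(out, net$species)
}

#' Binomial partitioning at division
#'
#' Splits a mother cell's molecules between two daughters: each molecule is
#' independently assigned to either daughter with probability 1/2, so
#' daughter counts are symmetric binomial and sum exactly to the mother's.
#'
#' @param counts Integer mother counts (per species).
#' @param seed Optional integer seed.
#' @return A list of two count vectors.
#' @export
divide_cell <- function(counts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  d1 <- stats::rbinom(length(counts), counts, 0.5)
  list(d1, counts - d1)
}

#' Agent-based simulation of a growing population
#'
#' Event-driven exact simulation of a lineage tree: each cell draws its
#' interdivision time at birth from \eqn{\phi}, runs exact stochastic
#' chemistry until division, and splits its molecules binomially between
#' two daughters. `mode = "tree"` keeps every cell (exponential growth);
#' `mode = "constant_N"` caps the population at `n_max` cells by removing
#' random cells at division events (chemostat), which reproduces balanced-
#' growth snapshot statistics at fixed memory.
#'
#' @param net A [reaction_network()].
#' @param model An [interdivision_model()] (parametric families only).
#' @param t_final Observation time; the returned snapshot is the set of
#'   cells alive at this time.
#' @param max_cells Alternative stop: halt when the population reaches this
#'   size (tree mode) and snapshot at that moment.
#' @param mode `"tree"` or `"constant_N"`.
#' @param n_max Population cap for `constant_N` mode.
#' @param x0 Initial molecule counts of the founder cell; defaults to the
#'   deterministic growth-shifted steady state (shortens burn-in).
#' @param seed Optional integer seed (fixed seed implies identical output).
#' @return A `"snapshot_table"`: data.frame with one row per live cell
#'   (columns `age`, `depth`, one per species), with attributes `time`,
#'   `growth` (population size at each division time), `mode`, `seed`.
#' @export
simulate_population <- function(net, model, t_final = NULL, max_cells = NULL,
                                mode = c("tree", "constant_N"), n_max = 1000L,
                                x0 = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot_idt(model)
  fc <- fam_code(model)
  if (is.null(t_final) && is.null(max_cells))
    stop("supply a stop condition: `t_final` or `max_cells`")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- default_x0(net, model)
  x0 <- as.integer(as_state(net, x0))
  res <- simulate_population_cpp(
    net_to_cpp(net), fc$code, fc$p1, fc$p2, x0,
    if (is.null(t_final)) Inf else t_final,
    if (mode == "constant_N") as.integer(n_max) else 0L,
    if (is.null(max_cells)) 0L else as.integer(max_cells))
  out <- data.frame(age = res$age, depth = res$depth)
  cn <- res$counts
  for (s in seq_along(net$species)) out[[net$species[s]]] <- cn[, s]
  structure(out, time = res$time,
            growth = data.frame(time = res$growth_t, n = res$growth_n),
            mode = mode, seed = seed, class = c("snapshot_table", "data.frame"))
}

#' Simulation of an isolated cell lineage
#'
#' Tracks a single cell through successive divisions (the mother-machine
#' setting): at each division one daughter is kept at random. States are
#' sampled on a fixed time grid so time-averaged statistics converge to the
#' lineage age distribution \eqn{\pi(\tau)}.
#'
#' @inheritParams simulate_population
#' @param n_divisions Number of recorded divisions (>= 1).
#' @param dt Sampling interval; default \eqn{E_\phi[\tau_d]/50}.
#' @param n_burn Burn-in divisions simulated and discarded before recording
#'   starts, so the trace samples the stationary lineage law rather than the
#'   founder state.
#' @return A `"lineage_trace"`: data.frame with columns `time`, `age` and
#'   one per species; attribute `division_times`.
#' @export
simulate_lineage <- function(net, model, n_divisions, dt = model$mean / 50,
                             n_burn = 10L, x0 = NULL, seed = NULL) {
  stopifnot_idt(model)
  stopifnot(n_divisions >= 1, dt > 0, n_burn >= 0)
  fc <- fam_code(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(x0)) x0 <- default_x0(net, model)
  x0 <- as.integer(as_state(net, x0))
  res <- simulate_lineage_cpp(net_to_cpp(net), fc$code, fc$p1, fc$p2, x0,
                              as.integer(n_divisions + n_burn), dt)
  divs <- res$division_times
  t0 <- if (n_burn > 0) divs[n_burn] else 0
  keep <- res$time > t0
  out <- data.frame(time = res$time[keep], age = res$age[keep])
  for (s in seq_along(net$species))
    out[[net$species[s]]] <- res$counts[keep, s]
  structure(out, division_times = divs[divs > t0], seed = seed,
            class = c("lineage_trace", "data.frame"))
}

reporter_pairs <- function(cols) {
  base <- sub("_1$", "", grep("_1$", cols, value = TRUE))
  base <- base[paste0(base, "_2") %in% cols]
  if (!length(base))
    stop("no dual-reporter species found (expected *_1 / *_2 column pairs ",
         "from duplicate_reporters())")
  base
}

estimate_one <- function(df, base) {
  x1 <- df[[paste0(base, "_1")]]
  x2 <- df[[paste0(base, "_2")]]
  m <- (mean(x1) + mean(x2)) / 2
  c(mean = m,
    sigma_int = mean((x1 - x2)^2) / 2,
    sigma_ext = mean(x1 * x2) - mean(x1) * mean(x2))
}

#' Empirical two-reporter noise decomposition
#'
#' Plug-in estimators of the dual-reporter decomposition from simulated (or
#' measured) cells carrying two identical, non-interacting copies of the
#' network: \eqn{\Sigma_{\mathrm{int}} = \frac{1}{2}E[(x_1-x_2)^2]},
#' \eqn{\Sigma_{\mathrm{ext}} = \mathrm{Cov}[x_1, x_2]}, pooled over all
#' cells (unknown-age decomposition) or per equal-count age bin. Standard
#' errors are bootstrapped over cells.
#'
#' @param x A `"snapshot_table"` or `"lineage_trace"` whose network was
#'   built by [duplicate_reporters()] (species columns `*_1`, `*_2`).
#' @param age_bins Optional number of equal-count age bins for age-resolved
#'   estimates.
#' @param n_boot Bootstrap replicates for standard errors (0 to skip).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with `pooled` (data.frame: species, mean, sigma_int,
#'   sigma_ext, sigma_tot and bootstrap SEs) and, if requested, `by_age`
#'   (the same per age bin, with mean bin age).
#' @export
estimate_decomposition <- function(x, age_bins = NULL, n_boot = 100L,
                                   seed = NULL) {
  df <- as.data.frame(x)
  if (!is.null(seed)) set.seed(seed)
  bases <- reporter_pairs(names(df))
  if (nrow(df) < 2L) stop("need at least 2 cells")

  pooled_for <- function(d) {
    est <- t(vapply(bases, function(b) estimate_one(d, b), numeric(3)))
    data.frame(species = bases, mean = est[, "mean"],
               sigma_int = est[, "sigma_int"], sigma_ext = est[, "sigma_ext"],
               sigma_tot = est[, "sigma_int"] + est[, "sigma_ext"],
               row.names = NULL)
  }
  pooled <- pooled_for(df)
  if (n_boot > 0) {
    boots <- replicate(n_boot, {
      d <- df[sample.int(nrow(df), replace = TRUE), , drop = FALSE]
      as.matrix(pooled_for(d)[, c("sigma_int", "sigma_ext", "sigma_tot",
                                  "mean")])
    })
    se <- apply(boots, c(1, 2), stats::sd)
    pooled$se_sigma_int <- se[, "sigma_int"]
    pooled$se_sigma_ext <- se[, "sigma_ext"]
    pooled$se_sigma_tot <- se[, "sigma_tot"]
    pooled$se_mean <- se[, "mean"]
  }
  out <- list(pooled = pooled)
  if (!is.null(age_bins)) {
    if (is.null(df$age)) stop("no `age` column for age-resolved estimates")
    bin <- ceiling(rank(df$age, ties.method = "first") / nrow(df) * age_bins)
    counts <- table(bin)
    if (any(counts < 2L)) stop("need >= 2 cells per age bin")
    by_age <- do.call(rbind, lapply(sort(unique(bin)), function(k) {
      d <- df[bin == k, , drop = FALSE]
      cbind(bin = k, age = mean(d$age), pooled_for(d))
    }))
    out$by_age <- by_age
  }
  out
}

#' Fit the exponential growth rate from a simulated tree
#'
#' Least-squares slope of log population size against time over the later
#' part of a tree-mode simulation (the early founder generations are
#' discarded as burn-in).
#'
#' @param snapshot A `"snapshot_table"` from tree-mode
#'   [simulate_population()].
#' @param burn_frac Fraction of division events discarded from the start.
#' @return Estimated growth rate (1/time).
#' @export
fit_growth_rate <- function(snapshot, burn_frac = 0.25) {
  g <- attr(snapshot, "growth")
  if (is.null(g) || nrow(g) < 10L) stop("no growth record to fit")
  keep <- seq(ceiling(nrow(g) * burn_frac), nrow(g))
  stats::coef(stats::lm(log(g$n[keep]) ~ g$time[keep]))[[2]]
}

#' Write a snapshot or lineage table with run metadata
#'
#' Serialises the table as a headered tab-separated file plus a YAML sidecar
#' (`<file>.meta.yaml`) carrying the run metadata (observation time, mode,
#' seed).
#'
#' @param x A `"snapshot_table"` or `"lineage_trace"`.
#' @param file Output path for the TSV.
#' @return `file`, invisibly.
#' @export
write_simulation <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(class = class(x)[1], time = attr(x, "time"),
               mode = attr(x, "mode"), seed = attr(x, "seed"),
               n_rows = nrow(x))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  yaml::write_yaml(meta, paste0(file, ".meta.yaml"))
  invisible(file)
}
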