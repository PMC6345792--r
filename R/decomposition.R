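new_decomposition <- function(ensemble, method, species, mean, sint, scc, sage) {
  sext <- scc + sage
  stot <- sint + sext
  mean <- stats::setNames(as.numeric(mean), species)
  cv2 <- function(S) stats::setNames(diag(as.matrix(S)) / mean^2, species)
  structure(list(ensemble = ensemble, method = method, species = species,
                 mean = mean,
                 sigma_int = sint, sigma_cc = scc, sigma_age = sage,
                 sigma_ext = sext, sigma_tot = stot,
                 cv2_int = cv2(sint), cv2_cc = cv2(scc), cv2_age = cv2(sage),
                 cv2_ext = cv2(sext), cv2_tot = cv2(stot)),
            class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat("Noise decomposition (", x$ensemble, ", method = ", x$method, ")\n",
      sep = "")
  print(as.data.frame(x), digits = 6)
  invisible(x)
}

#' @export
as.data.frame.noise_decomposition <- function(x, ...) {
  data.frame(species = x$species, ensemble = x$ensemble, method = x$method,
             mean = unname(x$mean), cv2_int = unname(x$cv2_int),
             cv2_cc = unname(x$cv2_cc), cv2_age = unname(x$cv2_age),
             cv2_ext = unname(x$cv2_ext), cv2_tot = unname(x$cv2_tot))
}

#' Age-averaged noise decomposition
#'
#' Averages converged age-resolved moments over the age distribution of the
#' ensemble, producing the unknown-age decomposition by the law of total
#' variance: \eqn{\bar\Sigma = \bar\Sigma_{\mathrm{int}} +
#' \bar\Sigma_{\mathrm{cc}} + \bar\Sigma_{\mathrm{age}}}, with
#' \eqn{\bar\Sigma_{\mathrm{int}} = E[\Sigma_{\mathrm{int}}(\tau)]} the
#' age-averaged intrinsic variance,
#' \eqn{\bar\Sigma_{\mathrm{cc}} = E[\Sigma_{\mathrm{ext}}(\tau)]} the
#' variance transmitted from cell-cycle duration fluctuations, and
#' \eqn{\bar\Sigma_{\mathrm{age}} = \mathrm{Cov}(E[x|\tau])} the dispersion
#' of the mean profile across cell ages. The latter two together form the
#' extrinsic (two-reporter covariance) component.
#'
#' @param am A converged `"age_moments"` object from
#'   [solve_cyclostationary()].
#' @return A `"noise_decomposition"` (method `"lna_numeric"`), carrying the
#'   component matrices and per-species CV^2 scalars (each species
#'   normalised by its own squared mean).
#' @export
age_average <- function(am) {
  if (!inherits(am, "age_moments")) stop("expected an `age_moments` object")
  if (!isTRUE(am$converged)) stop("age moments are not converged")
  ens <- ensemble_densities(am$ps, am$ensemble)
  avg <- profile_averages(am$profile, ens$age, 0, max(am$grid))
  new_decomposition(am$ensemble, "lna_numeric", am$net$species,
                    avg$mean, avg$sint, avg$sext, avg$cov_mean)
}

sylvester_shifted <- function(J, lambda, C) {
  # solve lambda X = J X + X J' + C  via  (A X + X A') = -C, A = J - lambda/2 I
  n <- nrow(J)
  A <- J - diag(lambda / 2, n)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  matrix(solve(K, -as.numeric(C)), n, n)
}

#' Exact algebraic decomposition for linear reaction networks
#'
#' For networks whose propensities are affine in the molecule numbers the
#' age-averaged decomposition can be computed algebraically instead of by
#' grid quadrature. In the population-snapshot ensemble the mean solves the
#' growth-shifted rate equations
#' \eqn{\lambda E[x] = \sum_r \nu_r w_r(E[x])}, and each component matrix
#' solves a shifted Lyapunov equation whose inhomogeneity carries the
#' division boundary terms, e.g.
#' \eqn{\lambda\bar\Sigma_{\mathrm{int}} = \mathcal{J}\bar\Sigma_{\mathrm{int}}
#' + \bar\Sigma_{\mathrm{int}}\mathcal{J}^T + \bar{\mathcal{D}} +
#' \lambda(2\Sigma_{\mathrm{int}}(0) - E_\rho[\Sigma_{\mathrm{int}}(\tau_d)])}.
#' The boundary quantities are consumed from a cyclo-stationary solve; only
#' the age-averaging step is replaced by algebra, which makes this an
#' independent cross-check of [age_average()].
#'
#' In the lineage ensemble no growth-rate identity is available (there is no
#' dilution term along a single lineage, and for singular Jacobians the
#' corresponding algebraic system is degenerate). There the affine moment
#' profiles are instead evaluated in closed form as matrix exponentials of
#' the stacked affine system and averaged against the lineage age
#' distribution \eqn{\pi} on fixed Gauss-Legendre panels -- a route that is
#' likewise independent of the ODE-grid quadrature.
#'
#' @inheritParams solve_cyclostationary
#' @param moments Optional converged `"age_moments"` for the same
#'   network/ensemble (computed on the fly when `NULL`); only its boundary
#'   and division-average quantities are used.
#' @return A `"noise_decomposition"` with method `"linear_exact"`.
#' @export
linear_exact <- function(net, ps, ensemble = c("population", "lineage"),
                         moments = NULL, ...) {
  ensemble <- match.arg(ensemble)
  if (!is_linear_network(net))
    stop("network has non-affine propensities; use ",
         "age_average(solve_cyclostationary(...)) instead")
  if (inherits(ps, "interdivision_model")) ps <- population_structure(ps)
  if (is.null(moments))
    moments <- solve_cyclostationary(net, ps, ensemble, ...)
  stopifnot(identical(moments$ensemble, ensemble))
  n <- net$n_species
  fns <- lna_fns(net)
  e0 <- fns$eval(numeric(n))
  J <- e0$J
  d0 <- e0$drift
  div <- moments$division
  birth <- moments$birth

  if (ensemble == "population") {
    lam <- ps$lambda
    Ex <- solve(J - diag(lam, n), -d0)
    Dbar <- fns$eval(Ex)$D
    sint <- sylvester_shifted(J, lam,
      Dbar + lam * (2 * birth$sigma_int - div$sint))
    scc <- sylvester_shifted(J, lam,
      lam * (2 * birth$sigma_ext - div$sext))
    sage <- sylvester_shifted(J, lam,
      lam * (tcrossprod(Ex) - 2 * tcrossprod(birth$mean) - div$cov_mean))
    return(new_decomposition("population", "linear_exact", net$species,
                             Ex, sint, scc, sage))
  }

  # lineage: closed-form affine profiles, averaged against pi(tau)
  q <- n * (n + 1) / 2
  # diffusion is affine in the mean: D(m) = D0 + sum_j m_j Dj
  D0 <- e0$D
  Dj <- lapply(seq_len(n), function(j) {
    ej <- numeric(n); ej[j] <- 1
    fns$eval(ej)$D - D0
  })
  Lyap <- matrix(0, q, q) # vech(J X + X J')
  for (k in seq_len(q)) {
    ek <- numeric(q); ek[k] <- 1
    Xk <- unvech(ek, n)
    Lyap[, k] <- vech(J %*% Xk + Xk %*% t(J))
  }
  dim_y <- n + 2 * q + 1
  A <- matrix(0, dim_y, dim_y)
  A[seq_len(n), seq_len(n)] <- J
  A[seq_len(n), dim_y] <- d0
  A[n + seq_len(q), n + seq_len(q)] <- Lyap
  for (j in seq_len(n)) A[n + seq_len(q), j] <- vech(Dj[[j]])
  A[n + seq_len(q), dim_y] <- vech(D0)
  A[n + q + seq_len(q), n + q + seq_len(q)] <- Lyap
  y0 <- c(birth$mean, vech(birth$sigma_int), vech(birth$sigma_ext), 1)

  model <- ps$model
  if (model$family == "deterministic") {
    breaks <- seq(0, ps$tau_max, length.out = 6L)
  } else {
    # panels follow phi's quantiles; the truncation matches the numeric
    # solver's lineage grid so both routes integrate the same support
    breaks <- c(0, idt_quantile(model,
      c(0.25, 0.5, 0.75, 0.9, 0.99, 0.999, 1 - 1e-4, 1 - 1e-6,
        1 - 1e-8, 1 - 1e-10)), idt_tau_max(model, 1e-13))
  }
  m_avg <- numeric(n); mm_avg <- matrix(0, n, n)
  si_avg <- numeric(q); se_avg <- numeric(q)
  agef <- ensemble_densities(ps, "lineage")$age
  for (p in seq_len(length(breaks) - 1L)) {
    gl <- pracma::gaussLegendre(40L, breaks[p], breaks[p + 1L])
    for (k in seq_along(gl$x)) {
      y <- as.numeric(as.matrix(Matrix::expm(A * gl$x[k])) %*% y0)
      wgt <- gl$w[k] * agef(gl$x[k])
      m <- y[seq_len(n)]
      m_avg <- m_avg + wgt * m
      mm_avg <- mm_avg + wgt * tcrossprod(m)
      si_avg <- si_avg + wgt * y[n + seq_len(q)]
      se_avg <- se_avg + wgt * y[n + q + seq_len(q)]
    }
  }
  new_decomposition("lineage", "linear_exact", net$species, m_avg,
                    unvech(si_avg, n), unvech(se_avg, n),
                    mm_avg - tcrossprod(m_avg))
}

#' Closed-form statistics of the bursty reporter
#'
#' Explicit formulas for a stable protein produced in geometric bursts (rate
#' `k0`, mean burst size `b`), with symmetric binomial partitioning at
#' division. With an age `tau` supplied, returns the age-resolved mean and
#' CV^2 components: writing \eqn{E_w} for the mean interdivision time under
#' the ensemble's division weighting (\eqn{\rho} for snapshots, \eqn{\phi}
#' for lineages),
#' \deqn{E[x|\tau] = k_0 b(\tau + E_w[\tau]),}
#' \deqn{CV^2_{\mathrm{int}}(\tau) = \frac{1}{E[x|\tau]}\left(1 +
#'   \tfrac{2}{3}b\Big[1 + \frac{2\tau}{E_w[\tau]+\tau}\Big]\right),}
#' \deqn{CV^2_{\mathrm{ext}}(\tau) =
#'   \frac{E_w[\tau]^2}{(E_w[\tau]+\tau)^2}\,\frac{CV_w^2}{3}.}
#' Without `tau`, returns the unknown-age (age-averaged) mean and the
#' intrinsic / transmitted cell-cycle / cell-age CV^2 components; the
#' snapshot mean is \eqn{k_0 b/\lambda} and the lineage mean
#' \eqn{b k_0 (E_\phi[\tau_d] + E_\pi[\tau])}.
#'
#' @param k0 Burst firing rate.
#' @param b Mean burst size.
#' @param ps A [population_structure()] (or [interdivision_model()]).
#' @param ensemble `"population"` or `"lineage"`.
#' @param tau Optional cell age(s); vectorised.
#' @return With `tau`: a data.frame with columns `tau`, `mean`, `cv2_int`,
#'   `cv2_ext`, `cv2_tot`. Without: a one-row data.frame with `mean`,
#'   `cv2_int`, `cv2_cc`, `cv2_age`, `cv2_ext`, `cv2_tot`.
#' @export
closed_form_bursty <- function(k0, b, ps, ensemble = c("population", "lineage"),
                               tau = NULL) {
  stopifnot(k0 > 0, b > 0)
  ensemble <- match.arg(ensemble)
  if (inherits(ps, "interdivision_model")) ps <- population_structure(ps)
  Ew <- if (ensemble == "population") ps$mean_rho else ps$mean_phi
  cv2w <- if (ensemble == "population") ps$cv2_rho else ps$cv2_phi
  if (!is.null(tau)) {
    m <- k0 * b * (tau + Ew)
    cv2_int <- (1 + (2 / 3) * b * (1 + 2 * tau / (Ew + tau))) / m
    cv2_ext <- (Ew / (Ew + tau))^2 * cv2w / 3
    return(data.frame(tau = tau, mean = m, cv2_int = cv2_int,
                      cv2_ext = cv2_ext, cv2_tot = cv2_int + cv2_ext))
  }
  if (ensemble == "population") {
    lam <- ps$lambda
    m <- k0 * b / lam
    cv2_int <- (1 + (2 / 3) * b * (1 + 2 * lam * ps$mean_Pi)) / m
    cv2_cc <- (ps$mean_rho * lam)^2 * ps$cv2_rho / 3
    cv2_age <- (lam * ps$mean_Pi)^2 * ps$cv2_Pi
  } else {
    tot <- ps$mean_phi + ps$mean_pi
    m <- b * k0 * tot
    cv2_int <- (1 + 2 * b - 4 * b * ps$mean_phi / (3 * tot)) / m
    cv2_cc <- ps$mean_phi^2 / tot^2 * ps$cv2_phi / 3
    cv2_age <- ps$mean_pi^2 / tot^2 * ps$cv2_pi
  }
  data.frame(mean = m, cv2_int = cv2_int, cv2_cc = cv2_cc, cv2_age = cv2_age,
             cv2_ext = cv2_cc + cv2_age, cv2_tot = cv2_int + cv2_cc + cv2_age)
}

#' Age at which intrinsic noise peaks
#'
#' For the bursty reporter the age-resolved intrinsic noise
#' \eqn{CV^2_{\mathrm{int}}(\tau)} has an interior maximum whenever the mean
#' burst size exceeds \eqn{3/2}; the maximising age, in units of the mean
#' interdivision time \eqn{E_\rho[\tau_d]}, is \eqn{(2b-3)/(6b+3)},
#' approaching \eqn{1/3} for large bursts. For \eqn{b \le 3/2} the noise is
#' monotonically decreasing in age and the function returns 0.
#'
#' @param b Mean burst size (vectorised).
#' @return The ratio \eqn{\tau^*/E_\rho[\tau_d]}.
#' @export
intrinsic_peak_age <- function(b) {
  stopifnot(all(b > 0))
  ifelse(b > 3 / 2, (2 * b - 3) / (6 * b + 3), 0)
}

#' Sweep the feedback strength of the autoregulatory circuit
#'
#' Runs the cyclo-stationary solver and age-averaged decomposition of the
#' negative-feedback network over a grid of dissociation constants `K` and
#' cell-cycle variabilities, for one or both ensembles. Solver failures at
#' individual grid points are recorded in the `status` column rather than
#' aborting the sweep.
#'
#' @param K_values Dissociation constants to sweep.
#' @param cv_values Interdivision-time coefficients of variation.
#' @param ensembles Character vector of ensembles to evaluate.
#' @param k0,km,ks,hill_n Circuit parameters (see [builtin_network()]).
#' @param family,mean Interdivision-time family and mean.
#' @param ... Passed to [solve_cyclostationary()].
#' @return A long-format data.frame keyed by `(K, cv_phi, ensemble, species)`
#'   with the mean and CV^2 component columns.
#' @export
sweep_feedback <- function(K_values, cv_values,
                           ensembles = c("population", "lineage"),
                           k0 = 10, km = 1, ks = 10, hill_n = 4,
                           family = "lognormal", mean = 1, ...) {
  out <- list()
  for (cv in cv_values) {
    ps <- population_structure(interdivision_model(family, mean = mean, cv = cv))
    for (K in K_values) {
      net <- builtin_network("negative_feedback", k0 = k0, km = km, ks = ks,
                             K = K, n = hill_n)
      for (ens in ensembles) {
        row <- tryCatch({
          dec <- age_average(solve_cyclostationary(net, ps, ens, ...))
          cbind(as.data.frame(dec), status = "ok")
        }, error = function(e) {
          data.frame(species = net$species, ensemble = ens,
                     method = "lna_numeric", mean = NA_real_,
                     cv2_int = NA_real_, cv2_cc = NA_real_,
                     cv2_age = NA_real_, cv2_ext = NA_real_,
                     cv2_tot = NA_real_, status = conditionMessage(e))
        })
        out[[length(out) + 1L]] <- cbind(K = K, cv_phi = cv, row)
      }
    }
  }
  do.call(rbind, out)
}

#' Feedback strength minimising a noise component
#'
#' Minimises a CV^2 component of the negative-feedback circuit over the
#' feedback strength \eqn{1/K}: a log-spaced grid over `K_range` locates the
#' basin, then golden-section refinement ([stats::optimize()]) polishes the
#' optimum to relative tolerance `tol` in \eqn{1/K}.
#'
#' @param objective Which component to minimise.
#' @param species Species whose component is minimised.
#' @param cv_phi Interdivision-time coefficient of variation.
#' @param ensemble `"population"` or `"lineage"`.
#' @param K_range Range of dissociation constants searched.
#' @param n_grid Coarse grid size.
#' @param tol Relative tolerance on \eqn{1/K}.
#' @inheritParams sweep_feedback
#' @return A list with `K_opt`, `inv_K_opt` and the minimised `value`.
#' @export
optimal_feedback <- function(objective = c("cv2_int", "cv2_cc"),
                             species = "Protein", cv_phi,
                             ensemble = c("population", "lineage"),
                             K_range = c(10, 1e4), n_grid = 13L, tol = 1e-4,
                             k0 = 10, km = 1, ks = 10, hill_n = 4,
                             family = "lognormal", mean = 1, ...) {
  objective <- match.arg(objective)
  ensemble <- match.arg(ensemble)
  ps <- population_structure(interdivision_model(family, mean = mean,
                                                 cv = cv_phi))
  obj <- function(logK) {
    net <- builtin_network("negative_feedback", k0 = k0, km = km, ks = ks,
                           K = exp(logK), n = hill_n)
    dec <- age_average(solve_cyclostationary(net, ps, ensemble, ...))
    dec[[objective]][[species]]
  }
  lg <- seq(log(K_range[1]), log(K_range[2]), length.out = n_grid)
  vals <- vapply(lg, obj, numeric(1))
  i <- which.min(vals)
  lo <- lg[max(i - 1L, 1L)]; hi <- lg[min(i + 1L, n_grid)]
  opt <- stats::optimize(obj, c(lo, hi), tol = tol)
  list(K_opt = exp(opt$minimum), inv_K_opt = exp(-opt$minimum),
       value = opt$objective)
}
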