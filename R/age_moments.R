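# --- symmetric-matrix packing -------------------------------------------------

vech_idx <- function(n) which(lower.tri(diag(n), diag = TRUE))
vech <- function(S) S[lower.tri(S, diag = TRUE)]
unvech <- function(v, n) {
  S <- matrix(0, n, n)
  S[lower.tri(S, diag = TRUE)] <- v
  S <- S + t(S)
  diag(S) <- diag(S) / 2
  S
}

# Precompiled drift/Jacobian/diffusion evaluator. Affine reactions (mass
# action of order <= 1, bursts) are folded into constant matrices so the ODE
# right-hand side reduces to a few small matrix products; Hill and
# higher-order mass-action reactions are evaluated per call.
lna_fns <- function(net) {
  n <- net$n_species
  simple <- vapply(net$reactions, function(r)
    r$type == "burst" || (r$type == "mass_action" && sum(r$nu_minus) <= 1),
    logical(1))
  rs <- net$reactions[simple]
  a <- vapply(rs, function(r) if (sum(r$nu_minus) == 0) r$rate else 0,
              numeric(1))
  G <- t(vapply(rs, function(r) {
    g <- numeric(n)
    j <- which(r$nu_minus > 0)
    if (length(j)) g[j] <- r$rate
    g
  }, numeric(n)))
  if (length(rs) == 0L) G <- matrix(0, 0, n)
  if (n == 1L && length(rs)) G <- matrix(G, ncol = n) # vapply collapses
  Nd <- vapply(rs, nu_drift, numeric(n))              # n x Rs drift stoich
  Bd <- vapply(rs, function(r) {
    if (r$type == "burst") {
      e <- numeric(n)
      e[match(r$species, names(r$nu))] <- sqrt(r$b * (2 * r$b + 1))
      e
    } else r$nu
  }, numeric(n))
  if (length(rs)) {
    Nd <- matrix(Nd, nrow = n); Bd <- matrix(Bd, nrow = n)
  } else {
    Nd <- Bd <- matrix(0, n, 0)
  }
  J0 <- Nd %*% G
  complex <- net$reactions[!simple]
  list(
    linear = length(complex) == 0L,
    eval = function(m) {
      w <- as.numeric(a + G %*% m)
      drift <- as.numeric(Nd %*% w)
      J <- J0
      D <- Bd %*% (w * t(Bd))
      for (r in complex) {
        wr <- prop_one(r, m)
        drift <- drift + r$nu * wr
        grad <- numeric(n)
        if (r$type == "hill") {
          j <- match(r$species, names(r$nu))
          p <- m[j]
          u <- (p / r$K)^r$n
          grad[j] <- if (p > 0) -r$rate * r$n * u / p / (1 + u)^2 else 0
        } else {
          for (j in which(r$nu_minus > 0)) {
            k <- r$nu_minus[j]
            oth <- prop_one(r, `[<-`(m, j, 1))
            grad[j] <- oth * k * m[j]^(k - 1)
          }
        }
        J <- J + outer(r$nu, grad)
        D <- D + tcrossprod(r$nu) * wr
      }
      list(drift = drift, J = J, D = D)
    })
}

#' Age grid for the moment solver
#'
#' Builds a strictly increasing grid on \eqn{[0, \tau_{\max}]} where
#' \eqn{\tau_{\max}} is the \eqn{(1 - \code{tail_p})} quantile of the
#' interdivision law. The interior nodes are composite Gauss-Legendre nodes
#' on panels that follow the quantiles of \eqn{\phi} into the tail; the
#' matching quadrature weights are attached as attribute `"gl_weights"`
#' (zero on the appended endpoints), so profile averages against any
#' density are computed with spectral accuracy directly at the ODE output
#' nodes, without interpolation.
#'
#' @param ps A [population_structure()].
#' @param n Approximate total number of nodes (default 400).
#' @param tail_p Tail mass of \eqn{\phi} discarded beyond \eqn{\tau_{\max}}.
#'   The default `1e-10` suffices for population averages (exponentially
#'   suppressed tails); lineage averages weight the bare \eqn{\phi}, whose
#'   second moments need a longer grid for long-tailed laws, so the solver
#'   uses `1e-13` there.
#' @return Numeric vector of ages with attribute `gl_weights`.
#' @export
age_grid <- function(ps, n = 400L, tail_p = 1e-10) {
  model <- ps$model
  tmax <- idt_tau_max(model, tail_p)
  if (model$family == "deterministic") {
    breaks <- seq(0, tmax, length.out = 12L)
  } else {
    probs <- c(0.1, 0.25, 0.5, 0.75, 0.9, 0.99, 0.999, 1 - 1e-4, 1 - 1e-6,
               1 - 1e-8, 1 - 1e-10, 1 - 1e-12)
    probs <- probs[probs < 1 - tail_p]
    breaks <- unique(c(0, idt_quantile(model, probs), tmax))
  }
  k <- max(8L, ceiling(n / (length(breaks) - 1L)))
  xs <- 0; ws <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    gl <- pracma::gaussLegendre(k, breaks[i], breaks[i + 1L])
    xs <- c(xs, gl$x); ws <- c(ws, gl$w)
  }
  xs <- c(xs, tmax); ws <- c(ws, 0)
  structure(xs, gl_weights = ws)
}

#' Propagate age-resolved LNA moments along the cell cycle
#'
#' Integrates the linear-noise-approximation moment equations along cell age
#' from a birth state: the mean follows the rate equations
#' \eqn{\partial_\tau E[x|\tau] = \sum_r \nu_r w_r(E[x|\tau])}, and the
#' intrinsic and extrinsic covariance components follow
#' \eqn{d\Sigma_{\mathrm{int}}/d\tau = \mathcal{J}\Sigma_{\mathrm{int}} +
#' \Sigma_{\mathrm{int}}\mathcal{J}^T + \mathcal{D}} and
#' \eqn{d\Sigma_{\mathrm{ext}}/d\tau = \mathcal{J}\Sigma_{\mathrm{ext}} +
#' \Sigma_{\mathrm{ext}}\mathcal{J}^T}, with \eqn{\mathcal{J}},
#' \eqn{\mathcal{D}} evaluated along the mean. Only the intrinsic component
#' receives the biochemical noise \eqn{\mathcal{D}}; the extrinsic component
#' is transported deterministically (it is fed only through the division
#' boundary condition, see [birth_update()]).
#'
#' @param net A [reaction_network()].
#' @param state0 Birth state: list with `mean` (length-n vector), `sigma_int`
#'   and `sigma_ext` (n x n PSD matrices).
#' @param grid Ages at which to report, from [age_grid()].
#' @param rtol,atol ODE integrator tolerances.
#' @return A list with `grid`, `mean` (M x n), `sint`, `sext` (M x n(n+1)/2,
#'   packed lower triangles), and the evaluator internals.
#' @export
propagate <- function(net, state0, grid, rtol = 1e-9, atol = 1e-12) {
  n <- net$n_species
  fns <- lna_fns(net)
  q <- n * (n + 1) / 2
  y0 <- c(state0$mean, vech(state0$sigma_int), vech(state0$sigma_ext))
  deriv <- function(t, y, parms) {
    m <- y[seq_len(n)]
    Si <- unvech(y[n + seq_len(q)], n)
    Se <- unvech(y[n + q + seq_len(q)], n)
    e <- fns$eval(m)
    JSi <- e$J %*% Si
    JSe <- e$J %*% Se
    list(c(e$drift, vech(JSi + t(JSi) + e$D), vech(JSe + t(JSe))))
  }
  sol <- deSolve::ode(y = y0, times = grid, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("age-moment ODE integration failed (istate = ",
         attr(sol, "istate")[1], ")")
  list(grid = grid,
       mean = sol[, 1 + seq_len(n), drop = FALSE],
       sint = sol[, 1 + n + seq_len(q), drop = FALSE],
       sext = sol[, 1 + n + q + seq_len(q), drop = FALSE],
       n = n)
}

# Average profile columns against a weighting density: Gauss-Legendre sums
# at the grid nodes when the grid carries quadrature weights, adaptive
# quadrature on a spline interpolant otherwise.
profile_averages <- function(prof, dens, lower, upper) {
  ws <- attr(prof$grid, "gl_weights")
  if (!is.null(ws)) {
    wd <- ws * dens(as.numeric(prof$grid))
    avg_col <- function(vals) sum(wd * vals)
  } else {
    avg_col <- function(vals) {
      f <- stats::splinefun(prof$grid, vals, method = "fmm")
      quad(function(t) f(t) * dens(t), lower, upper,
           rel.tol = 1e-10, abs.tol = 1e-14)
    }
  }
  n <- prof$n
  mean_w <- unname(apply(prof$mean, 2, avg_col))
  sint_w <- unvech(apply(prof$sint, 2, avg_col), n)
  sext_w <- unvech(apply(prof$sext, 2, avg_col), n)
  # second moment of the mean profile, for the outer-product covariance
  idx <- which(lower.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  mm <- unvech(apply(idx, 1, function(ij)
    avg_col(prof$mean[, ij[1]] * prof$mean[, ij[2]])), n)
  list(mean = mean_w, sint = sint_w, sext = sext_w,
       cov_mean = mm - tcrossprod(mean_w))
}

#' Division averages of age-resolved profiles
#'
#' Averages the mean and covariance profiles over the age at division, i.e.
#' against the division-weighting density of the chosen ensemble
#' (\eqn{\rho(\tau_d)} for population snapshots, \eqn{\phi(\tau_d)} for
#' lineages). Returns every quantity entering the birth boundary condition:
#' \eqn{E_w[E[x|\tau_d]]}, \eqn{E_w[\Sigma_{\mathrm{int}}(\tau_d)]},
#' \eqn{E_w[\Sigma_{\mathrm{ext}}(\tau_d)]} and the cell-cycle covariance
#' \eqn{\mathrm{Cov}_w[E[x|\tau_d]]} (the outer-product covariance of the
#' mean profile under \eqn{w}). For a deterministic interdivision time the
#' averages are point evaluations at \eqn{T}.
#'
#' @param prof Output of [propagate()].
#' @param ps A [population_structure()].
#' @param ensemble `"population"` or `"lineage"`.
#' @return A list `mean`, `sint`, `sext`, `cov_mean`.
#' @export
division_averages <- function(prof, ps, ensemble = c("population", "lineage")) {
  ensemble <- match.arg(ensemble)
  model <- ps$model
  if (max(prof$grid) < ps$tau_max * (1 - 1e-9))
    stop("profile grid does not cover the support of the division density")
  if (model$family == "deterministic") {
    n <- prof$n
    at_T <- function(vals) {
      stats::splinefun(prof$grid, vals, method = "fmm")(model$mean)
    }
    return(list(mean = unname(apply(prof$mean, 2, at_T)),
                sint = unvech(apply(prof$sint, 2, at_T), n),
                sext = unvech(apply(prof$sext, 2, at_T), n),
                cov_mean = matrix(0, n, n)))
  }
  ens <- ensemble_densities(ps, ensemble)
  profile_averages(prof, ens$division, 0, max(prof$grid))
}

#' Birth state from division averages
#'
#' Applies the cell-division boundary conditions. Means halve:
#' \eqn{E[x|0] = \frac{1}{2}E_w[E[x|\tau_d]]}. With symmetric binomial
#' partitioning (each molecule independently assigned to either daughter,
#' \eqn{\mathrm{Cov}_B = \mathrm{diag}(x')/4}) the covariance components
#' satisfy
#' \eqn{4\Sigma_{\mathrm{int}}(0) = E_w[\Sigma_{\mathrm{int}}(\tau_d)] +
#' E_w[\mathrm{diag}(E[x|\tau_d])]} (intrinsic noise in the mother plus
#' partitioning noise) and
#' \eqn{4\Sigma_{\mathrm{ext}}(0) = E_w[\Sigma_{\mathrm{ext}}(\tau_d)] +
#' \mathrm{Cov}_w[E[x|\tau_d]]} (extrinsic noise in the mother plus
#' cell-cycle noise).
#'
#' @param divavg Output of [division_averages()].
#' @param kernel `"binomial"` (default), or a list with a function
#'   `cov_b(mean_division)` returning the expected partitioning covariance
#'   matrix \eqn{E[\mathrm{Cov}_B]} at the division-average mean. Custom
#'   kernels must still split means equally (\eqn{E_B[x|x'] = x'/2}); a
#'   kernel declaring `mean_fraction` different from 1/2 is rejected.
#' @return A list `mean`, `sigma_int`, `sigma_ext` (the birth state).
#' @export
birth_update <- function(divavg, kernel = "binomial") {
  n <- length(divavg$mean)
  if (identical(kernel, "binomial")) {
    part <- diag(divavg$mean, n) / 4
  } else if (is.list(kernel) && is.function(kernel$cov_b)) {
    if (!is.null(kernel$mean_fraction) && kernel$mean_fraction != 0.5)
      stop("partitioning kernels must split means equally: E_B[x|x'] = x'/2")
    part <- kernel$cov_b(divavg$mean)
    if (!isTRUE(all.equal(dim(part), c(n, n))))
      stop("kernel$cov_b must return an n x n matrix")
  } else {
    stop("`kernel` must be \"binomial\" or a list with a cov_b function")
  }
  list(mean = divavg$mean / 2,
       sigma_int = (divavg$sint + 4 * part) / 4,
       sigma_ext = (divavg$sext + divavg$cov_mean) / 4)
}

# Deterministic initial guess: damped Euler relaxation of the rate equations
# with a dilution term -lambda x, started from zero.
init_birth_state <- function(net, ps) {
  fns <- lna_fns(net)
  lam <- ps$lambda
  m <- numeric(net$n_species)
  dt <- 0.1 / lam
  for (i in seq_len(5000L)) {
    g <- fns$eval(m)$drift - lam * m
    m2 <- pmax(m + dt * g, 0)
    if (max(abs(m2 - m)) <= 1e-12 * max(1, max(abs(m2)))) { m <- m2; break }
    m <- m2
  }
  list(mean = m / 2, sigma_int = diag(pmax(m, 1), net$n_species),
       sigma_ext = matrix(0, net$n_species, net$n_species))
}

#' Cyclo-stationary age-resolved moments
#'
#' Solves the age-resolved LNA moment equations subject to the cell-division
#' boundary conditions for the chosen ensemble, by shooting: starting from a
#' deterministic initial guess, the birth state is propagated along the cell
#' cycle ([propagate()]), averaged at division ([division_averages()]) and
#' mapped back through the division kernel ([birth_update()]); the damped
#' fixed-point iteration stops when the birth state is self-consistent to
#' relative tolerance `tol`. For affine-propensity networks the fixed-point
#' map is affine and the iteration converges geometrically; for the Hill
#' feedback circuit it is contractive in practice.
#'
#' @inheritParams propagate
#' @param ps A [population_structure()].
#' @param ensemble `"population"` (snapshot statistics, division weighting
#'   \eqn{\rho}) or `"lineage"` (mother machine, weighting \eqn{\phi}).
#' @param tol Relative sup-norm tolerance on the birth state (default 1e-8).
#' @param max_iter Maximum fixed-point iterations.
#' @param damping Fixed-point damping in (0, 1]; the update is
#'   `(1-damping)*old + damping*new`.
#' @param grid_n Approximate number of age-grid intervals.
#' @param kernel Partitioning kernel, see [birth_update()].
#' @param init Optional birth-state list to start from.
#' @return An object of class `"age_moments"`: fields `grid`, `mean`
#'   (M x n), `sigma_int`, `sigma_ext` (M x n x n arrays), `birth`,
#'   `division` (the converged division averages), `ensemble`, `converged`,
#'   `boundary_residual`, `iterations`, plus the inputs.
#' @examples
#' \donttest{
#' ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
#' net <- builtin_network("bursty_reporter", k0 = 1, b = 100)
#' am <- solve_cyclostationary(net, ps)
#' head(am$mean) # k0 b (tau + E_rho[tau])
#' }
#' @export
solve_cyclostationary <- function(net, ps, ensemble = c("population", "lineage"),
                                  tol = 1e-8, max_iter = 200L, damping = 0.5,
                                  grid_n = 400L, kernel = "binomial",
                                  init = NULL, rtol = 1e-9, atol = 1e-12) {
  ensemble <- match.arg(ensemble)
  stopifnot(tol > 0, damping > 0, damping <= 1)
  if (inherits(ps, "interdivision_model")) ps <- population_structure(ps)
  grid <- age_grid(ps, grid_n,
                   tail_p = if (ensemble == "lineage") 1e-13 else 1e-10)
  n <- net$n_species
  state <- if (is.null(init)) init_birth_state(net, ps) else init
  pack <- function(s) c(s$mean, vech(s$sigma_int), vech(s$sigma_ext))
  q <- n * (n + 1) / 2
  unpack <- function(v) list(mean = v[seq_len(n)],
                             sigma_int = unvech(v[n + seq_len(q)], n),
                             sigma_ext = unvech(v[n + q + seq_len(q)], n))
  xi <- pack(state)
  converged <- FALSE
  resid <- Inf
  prof <- NULL; divavg <- NULL
  for (it in seq_len(max_iter)) {
    prof <- propagate(net, unpack(xi), grid, rtol = rtol, atol = atol)
    divavg <- division_averages(prof, ps, ensemble)
    xi_new <- pack(birth_update(divavg, kernel))
    resid <- max(abs(xi_new - xi) / pmax(abs(xi), 1)) # per-component relative
    if (resid <= tol) {
      xi <- xi_new
      converged <- TRUE
      break
    }
    xi <- (1 - damping) * xi + damping * xi_new
  }
  if (!converged)
    stop("shooting iteration did not converge in ", max_iter,
         " iterations (last residual ", format(resid), ")")
  # final propagation from the converged birth state
  prof <- propagate(net, unpack(xi), grid, rtol = rtol, atol = atol)
  divavg <- division_averages(prof, ps, ensemble)
  M <- length(grid)
  si <- array(0, c(M, n, n)); se <- array(0, c(M, n, n))
  for (k in seq_len(M)) {
    si[k, , ] <- unvech(prof$sint[k, ], n)
    se[k, , ] <- unvech(prof$sext[k, ], n)
  }
  colnames(prof$mean) <- net$species
  structure(list(grid = grid, mean = prof$mean, sigma_int = si, sigma_ext = se,
                 profile = prof, birth = unpack(xi), division = divavg,
                 ensemble = ensemble, converged = converged,
                 boundary_residual = resid, iterations = it,
                 net = net, ps = ps),
            class = "age_moments")
}

#' @export
print.age_moments <- function(x, ...) {
  cat("Age-resolved LNA moments (", x$ensemble, " ensemble, ",
      length(x$grid), " ages, ", x$net$n_species, " species)\n", sep = "")
  cat(sprintf("  converged: %s after %d iterations (boundary residual %.2e)\n",
              x$converged, x$iterations, x$boundary_residual))
  cat("  birth mean:", format(x$birth$mean, digits = 6), "\n")
  invisible(x)
}

#' Export age-resolved moments as a table
#'
#' One row per grid age with the per-species mean and the flattened
#' intrinsic/extrinsic covariance components; suitable for writing with
#' [utils::write.table()].
#'
#' @param x An `"age_moments"` object.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.age_moments <- function(x, ...) {
  n <- x$net$n_species
  sp <- x$net$species
  out <- data.frame(age = x$grid)
  for (i in seq_len(n)) out[[paste0("mean_", sp[i])]] <- x$mean[, i]
  for (i in seq_len(n)) for (j in seq_len(i))
    out[[paste0("sint_", sp[i], "_", sp[j])]] <- x$sigma_int[, i, j]
  for (i in seq_len(n)) for (j in seq_len(i))
    out[[paste0("sext_", sp[i], "_", sp[j])]] <- x$sigma_ext[, i, j]
  out
}
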