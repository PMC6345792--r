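#' Population growth rate from the Euler-Lotka equation
#'
#' Solves \eqn{1 = 2\int_0^\infty e^{-\lambda \tau_d}\phi(\tau_d)\,d\tau_d}
#' for the exponential growth rate \eqn{\lambda} of a population in balanced
#' growth. The left-hand side is strictly decreasing in \eqn{\lambda}, so the
#' root is unique; it is bracketed by doubling and polished with
#' [stats::uniroot()] to near machine precision.
#'
#' @inheritParams idt_density
#' @return Growth rate \eqn{\lambda > 0} (1/time), with Euler-Lotka residual
#'   \eqn{|2\int e^{-\lambda\tau_d}\phi - 1| \le 10^{-10}}.
#' @examples
#' growth_rate(interdivision_model("deterministic", mean = 1)) # log(2)
#' @export
growth_rate <- function(model) {
  stopifnot_idt(model)
  lam <- switch(model$family,
    exponential = model$rate,
    gamma = model$rate * (2^(1 / model$shape) - 1),
    deterministic = log(2) / model$mean,
    {
      f <- function(l) 2 * idt_laplace(model, l) - 1
      hi <- 1 / model$mean
      while (f(hi) > 0) hi <- hi * 2
      stats::uniroot(f, c(1e-12, hi), tol = 1e-14)$root
    })
  resid <- abs(2 * idt_laplace(model, lam) - 1)
  if (resid > 1e-10)
    stop("Euler-Lotka residual ", format(resid), " exceeds 1e-10")
  lam
}

#' Interdivision-time distribution in the population
#'
#' In a snapshot of a growing population, cells with completed divisions have
#' interdivision times distributed as
#' \eqn{\rho(\tau_d) = 2\phi(\tau_d)e^{-\lambda\tau_d}}: fast-dividing cells
#' are over-represented relative to the single-cell law \eqn{\phi}. The
#' Euler-Lotka equation guarantees normalisation.
#'
#' @inheritParams idt_density
#' @param lambda Population growth rate; computed via [growth_rate()] when
#'   `NULL`. A supplied value inconsistent with the model (normalisation off
#'   by more than `1e-6`) raises an error.
#' @return Density values \eqn{\rho(\tau_d)}.
#' @export
population_division_density <- function(model, tau, lambda = NULL) {
  stopifnot_idt(model)
  if (is.null(lambda)) {
    lambda <- growth_rate(model)
  } else if (abs(2 * idt_laplace(model, lambda) - 1) > 1e-6) {
    stop("`lambda` is inconsistent with the interdivision model: ",
         "2*Laplace(lambda) deviates from 1 by more than 1e-6")
  }
  2 * idt_density(model, tau) * exp(-lambda * tau)
}

#' Population structure under balanced growth
#'
#' Aggregates the age structure of a growing population: the growth rate
#' \eqn{\lambda}, and means / squared coefficients of variation of the four
#' densities of the framework — the single-cell interdivision law
#' \eqn{\phi(\tau_d)}, its population-weighted counterpart
#' \eqn{\rho(\tau_d) = 2\phi e^{-\lambda\tau_d}}, the snapshot age
#' distribution \eqn{\Pi(\tau) = 2\lambda e^{-\lambda\tau}S(\tau)} and the
#' lineage age distribution \eqn{\pi(\tau) = S(\tau)/E_\phi[\tau_d]}, where
#' \eqn{S} is the survival function of \eqn{\phi}.
#'
#' All moments are computed by adaptive quadrature (closed forms for the
#' deterministic point mass). The object satisfies, within quadrature
#' tolerance, the consistency identities
#' \eqn{E_\rho[\tau_d] \le E_\phi[\tau_d]} and
#' \eqn{E_\Pi[\tau] + E_\rho[\tau_d] = 1/\lambda}.
#'
#' @inheritParams idt_density
#' @return An object of class `"population_structure"` with fields `model`,
#'   `lambda`, `euler_lotka_residual`, `tau_max` and, for each density `d` in
#'   `phi`, `rho`, `Pi`, `pi`: `mean_d` and `cv2_d`.
#' @examples
#' ps <- population_structure(interdivision_model("exponential", mean = 1))
#' ps$lambda            # 1
#' ps$mean_rho          # 1/2
#' @export
population_structure <- function(model) {
  stopifnot_idt(model)
  lambda <- growth_rate(model)
  mom <- idt_moments(model)

  if (model$family == "deterministic") {
    T_ <- model$mean
    mean_rho <- T_; m2_rho <- T_^2
    mean_Pi <- quad(function(t) t * 2 * lambda * exp(-lambda * t), 0, T_)
    m2_Pi <- quad(function(t) t^2 * 2 * lambda * exp(-lambda * t), 0, T_)
    mean_pi <- T_ / 2; m2_pi <- T_^2 / 3
    resid <- abs(2 * exp(-lambda * T_) - 1)
  } else {
    rho <- function(t) 2 * idt_density(model, t) * exp(-lambda * t)
    mean_rho <- quad(function(t) t * rho(t), 0, Inf)
    m2_rho <- quad(function(t) t^2 * rho(t), 0, Inf)
    Pi <- function(t) 2 * lambda * exp(-lambda * t) * idt_survival(model, t)
    mean_Pi <- quad(function(t) t * Pi(t), 0, Inf)
    m2_Pi <- quad(function(t) t^2 * Pi(t), 0, Inf)
    # E_pi moments via survival-function identities:
    #   \int t^k S(t) dt = E_phi[tau^{k+1}]/(k+1)
    mean_pi <- mom$m2 / (2 * mom$mean)
    m3 <- switch(model$family,
      exponential = 6 * model$mean^3,
      gamma = model$mean^3 * (1 + 1 / model$shape) * (1 + 2 / model$shape),
      lognormal = model$mean^3 * (1 + model$cv^2)^3,
      quad(function(t) t^3 * idt_density(model, t), 0, Inf))
    m2_pi <- m3 / (3 * mom$mean)
    resid <- abs(2 * idt_laplace(model, lambda) - 1)
  }

  cv2 <- function(m1, m2) max(m2 - m1^2, 0) / m1^2
  structure(list(
    model = model, lambda = lambda, euler_lotka_residual = resid,
    tau_max = idt_tau_max(model),
    mean_phi = mom$mean, cv2_phi = mom$cv2,
    mean_rho = mean_rho, cv2_rho = cv2(mean_rho, m2_rho),
    mean_Pi = mean_Pi, cv2_Pi = cv2(mean_Pi, m2_Pi),
    mean_pi = mean_pi, cv2_pi = cv2(mean_pi, m2_pi)),
    class = "population_structure")
}

#' @export
print.population_structure <- function(x, ...) {
  cat("Population structure (", x$model$family, " interdivision times, mean ",
      format(x$model$mean), ", cv ", format(x$model$cv), ")\n", sep = "")
  cat(sprintf("  growth rate lambda = %.8g (Euler-Lotka residual %.2e)\n",
              x$lambda, x$euler_lotka_residual))
  cat(sprintf("  E_phi[tau_d] = %.6g  CV2_phi = %.6g\n", x$mean_phi, x$cv2_phi))
  cat(sprintf("  E_rho[tau_d] = %.6g  CV2_rho = %.6g\n", x$mean_rho, x$cv2_rho))
  cat(sprintf("  E_Pi[tau]    = %.6g  CV2_Pi  = %.6g\n", x$mean_Pi, x$cv2_Pi))
  cat(sprintf("  E_pi[tau]    = %.6g  CV2_pi  = %.6g\n", x$mean_pi, x$cv2_pi))
  invisible(x)
}

#' Age distribution of a snapshot or a lineage
#'
#' Under balanced growth the fraction of cells of age \eqn{\tau} is
#' \eqn{\Pi(\tau) = 2\lambda e^{-\lambda\tau} S(\tau)} across a population
#' snapshot, and \eqn{\pi(\tau) = S(\tau)/E_\phi[\tau_d]} along an isolated
#' lineage (mother machine), where \eqn{S} is the survival function of the
#' interdivision-time law.
#'
#' @param ps A [population_structure()] (or an [interdivision_model()], in
#'   which case the structure is computed on the fly).
#' @param tau Ages (vectorised).
#' @param ensemble `"population"` or `"lineage"`.
#' @return Density values.
#' @export
age_density <- function(ps, tau, ensemble = c("population", "lineage")) {
  ensemble <- match.arg(ensemble)
  if (inherits(ps, "interdivision_model")) ps <- population_structure(ps)
  if (!inherits(ps, "population_structure"))
    stop("`ps` must be a population_structure or interdivision_model")
  s <- idt_survival(ps$model, tau)
  if (ensemble == "population") 2 * ps$lambda * exp(-ps$lambda * tau) * s
  else s / ps$mean_phi
}

#' Ensemble accessors
#'
#' The lineage statistics of the framework are obtained from the population
#' ones by substituting the interdivision-time distribution
#' \eqn{\rho(\tau_d) \to \phi(\tau_d)} and the age distribution
#' \eqn{\Pi(\tau) \to \pi(\tau)}. This helper returns the pair of densities
#' (division-weighting and age) for the requested ensemble, plus the matching
#' summary moments, so downstream code is ensemble-agnostic.
#'
#' @inheritParams age_density
#' @return A list with functions `division(tau)` and `age(tau)` and scalars
#'   `division_mean`, `division_cv2`, `age_mean`, `age_cv2`, `ensemble`.
#' @export
ensemble_densities <- function(ps, ensemble = c("population", "lineage")) {
  ensemble <- match.arg(ensemble)
  if (inherits(ps, "interdivision_model")) ps <- population_structure(ps)
  model <- ps$model
  if (ensemble == "population") {
    lam <- ps$lambda
    list(ensemble = ensemble,
         division = function(tau) 2 * idt_density(model, tau) * exp(-lam * tau),
         age = function(tau) age_density(ps, tau, "population"),
         division_mean = ps$mean_rho, division_cv2 = ps$cv2_rho,
         age_mean = ps$mean_Pi, age_cv2 = ps$cv2_Pi)
  } else {
    list(ensemble = ensemble,
         division = function(tau) idt_density(model, tau),
         age = function(tau) age_density(ps, tau, "lineage"),
         division_mean = ps$mean_phi, division_cv2 = ps$cv2_phi,
         age_mean = ps$mean_pi, age_cv2 = ps$cv2_pi)
  }
}
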