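#' Interdivision-time model
#'
#' Constructs the single-cell interdivision-time law \eqn{\phi(\tau_d)}, the
#' distribution of times between a cell's birth and its division. The model is
#' the basic ingredient of the population framework: it determines the
#' age-dependent division hazard \eqn{\gamma(\tau)}, the population growth
#' rate and all age structure (see [population_structure()]).
#'
#' Supported families:
#' \describe{
#'   \item{exponential}{memoryless division, constant hazard \eqn{1/\code{mean}};
#'     `cv` is fixed at 1.}
#'   \item{gamma}{parameterised by `mean` and either `cv` or `shape`
#'     (\eqn{\alpha = 1/\mathrm{cv}^2}).}
#'   \item{lognormal}{parameterised by `mean` and `cv`; converted internally to
#'     log-scale parameters \eqn{\sigma^2 = \log(1+\mathrm{cv}^2)},
#'     \eqn{\mu = \log(\code{mean}) - \sigma^2/2}.}
#'   \item{deterministic}{point mass at \eqn{\tau_d = \code{mean}}; integrals
#'     against \eqn{\phi} reduce to point evaluation.}
#'   \item{custom}{user-supplied density callable on \eqn{[0,\infty)}. The
#'     density must be proper (integrate to 1) with finite positive mean;
#'     improper densities (equivalently, hazards with integrable tails) are
#'     rejected.}
#' }
#'
#' @param family One of `"exponential"`, `"gamma"`, `"lognormal"`,
#'   `"deterministic"`, `"custom"`.
#' @param mean Mean interdivision time \eqn{E_\phi[\tau_d]} (time units).
#'   Ignored for `family = "custom"` (computed from the density).
#' @param cv Coefficient of variation of \eqn{\tau_d} (dimensionless).
#' @param shape Gamma shape parameter \eqn{\alpha}; alternative to `cv` for
#'   `family = "gamma"`.
#' @param density For `family = "custom"`: a vectorised density function on
#'   \eqn{[0,\infty)}.
#' @return An object of class `"interdivision_model"`.
#' @examples
#' m <- interdivision_model("gamma", mean = 1, cv = 0.5)
#' idt_density(m, 1)
#' hazard_rate(m, 1)
#' @export
interdivision_model <- function(family = c("exponential", "gamma", "lognormal",
                                           "deterministic", "custom"),
                                mean = 1, cv = NULL, shape = NULL,
                                density = NULL) {
  family <- match.arg(family)
  if (family != "custom") {
    if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
      stop("`mean` must be a finite, strictly positive number")
  }
  m <- switch(family,
    exponential = {
      if (!is.null(cv) && abs(cv - 1) > 1e-12)
        stop("exponential interdivision times have cv = 1; got cv = ", cv)
      list(family = family, mean = mean, cv = 1, rate = 1 / mean)
    },
    gamma = {
      if (is.null(shape)) {
        if (is.null(cv)) stop("gamma family needs `cv` or `shape`")
        shape <- 1 / cv^2
      } else if (!is.null(cv) && abs(shape - 1 / cv^2) > 1e-8 * shape) {
        stop("`cv` and `shape` are inconsistent: shape = 1/cv^2 required")
      }
      if (shape <= 0) stop("gamma shape must be positive")
      list(family = family, mean = mean, cv = 1 / sqrt(shape),
           shape = shape, rate = shape / mean)
    },
    lognormal = {
      if (is.null(cv) || cv <= 0) stop("lognormal family needs `cv` > 0")
      sigma2 <- log(1 + cv^2)
      list(family = family, mean = mean, cv = cv,
           meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    deterministic = {
      if (!is.null(cv) && cv != 0)
        stop("deterministic interdivision times have cv = 0")
      list(family = family, mean = mean, cv = 0)
    },
    custom = {
      if (!is.function(density)) stop("custom family needs a `density` function")
      total <- quad(density, 0, Inf)
      if (abs(total - 1) > 1e-6)
        stop("custom density must integrate to 1 (got ", format(total),
             "); improper interdivision laws are rejected")
      mu <- quad(function(t) t * density(t), 0, Inf)
      if (!is.finite(mu) || mu <= 0)
        stop("custom density must have a finite, strictly positive mean")
      m2 <- quad(function(t) t^2 * density(t), 0, Inf)
      list(family = family, mean = mu, cv = sqrt(max(m2 - mu^2, 0)) / mu,
           density = density)
    })
  structure(m, class = "interdivision_model")
}

#' @export
print.interdivision_model <- function(x, ...) {
  cat("Interdivision-time model:", x$family,
      sprintf("(mean = %g, cv = %g)\n", x$mean, x$cv))
  invisible(x)
}

stopifnot_idt <- function(model) {
  if (!inherits(model, "interdivision_model"))
    stop("expected an `interdivision_model` object")
}

#' Interdivision-time density, survival, quantile
#'
#' `idt_density` evaluates \eqn{\phi(\tau_d)}, `idt_survival` the survival
#' function \eqn{S(\tau) = \int_\tau^\infty \phi}, and `idt_quantile` the
#' quantile function. For the deterministic family the density is a point
#' mass; `idt_density` returns `Inf` at the atom and 0 elsewhere.
#'
#' @param model An [interdivision_model()].
#' @param tau Ages / interdivision times (vectorised, nonnegative).
#' @param p Probabilities in \eqn{[0,1)}.
#' @return Numeric vector.
#' @export
idt_density <- function(model, tau) {
  stopifnot_idt(model)
  out <- switch(model$family,
    exponential = stats::dexp(tau, rate = model$rate),
    gamma = stats::dgamma(tau, shape = model$shape, rate = model$rate),
    lognormal = stats::dlnorm(tau, meanlog = model$meanlog, sdlog = model$sdlog),
    deterministic = ifelse(tau == model$mean, Inf, 0),
    custom = model$density(tau))
  out[tau < 0] <- 0
  out
}

#' @rdname idt_density
#' @export
idt_survival <- function(model, tau) {
  stopifnot_idt(model)
  out <- switch(model$family,
    exponential = stats::pexp(tau, rate = model$rate, lower.tail = FALSE),
    gamma = stats::pgamma(tau, shape = model$shape, rate = model$rate,
                          lower.tail = FALSE),
    lognormal = stats::plnorm(tau, meanlog = model$meanlog, sdlog = model$sdlog,
                              lower.tail = FALSE),
    deterministic = as.numeric(tau < model$mean),
    custom = vapply(tau, function(t) {
      if (t <= 0) return(1)
      max(0, min(1, quad(model$density, t, Inf)))
    }, numeric(1)))
  out[tau < 0] <- 1
  out
}

#' @rdname idt_density
#' @export
idt_quantile <- function(model, p) {
  stopifnot_idt(model)
  switch(model$family,
    exponential = stats::qexp(p, rate = model$rate),
    gamma = stats::qgamma(p, shape = model$shape, rate = model$rate),
    lognormal = stats::qlnorm(p, meanlog = model$meanlog, sdlog = model$sdlog),
    deterministic = rep(model$mean, length(p)),
    custom = vapply(p, function(pp) {
      if (pp <= 0) return(0)
      f <- function(t) (1 - idt_survival(model, t)) - pp
      hi <- model$mean
      while (f(hi) < 0) hi <- hi * 2
      stats::uniroot(f, c(0, hi), tol = 1e-12)$root
    }, numeric(1)))
}

#' Age-dependent division hazard from the interdivision-time law
#'
#' Cells divide with an age-dependent rate
#' \eqn{\gamma(\tau) = \phi(\tau) / \int_\tau^\infty \phi(\tau_d)\,d\tau_d},
#' the hazard of the interdivision-time distribution.
#'
#' @inheritParams idt_density
#' @return The division rate \eqn{\gamma(\tau)} (1/time), vectorised over `tau`.
#' @details For the deterministic family the hazard is singular at the
#'   division age and an error is raised for \eqn{\tau \ge T}. An error is
#'   also raised when the survival probability underflows ("beyond support").
#' @export
hazard_rate <- function(model, tau) {
  stopifnot_idt(model)
  if (model$family == "deterministic") {
    if (any(tau >= model$mean))
      stop("deterministic hazard is singular at tau >= T")
    return(rep(0, length(tau)))
  }
  s <- idt_survival(model, tau)
  if (any(s <= 1e-280))
    stop("survival underflow: age beyond support of the interdivision law")
  idt_density(model, tau) / s
}

#' Interdivision-time density from an age-dependent hazard
#'
#' Inverts the hazard relation:
#' \eqn{\phi(\tau_d) = \gamma(\tau_d)\exp(-\int_0^{\tau_d}\gamma(\tau)\,d\tau)}.
#' Round-trips with [hazard_rate()] on smooth families.
#'
#' @param hazard A vectorised, nonnegative hazard function of age.
#' @param tau Interdivision times at which to evaluate the density.
#' @return Density values \eqn{\phi(\tau_d)}.
#' @export
density_from_hazard <- function(hazard, tau) {
  if (!is.function(hazard)) stop("`hazard` must be a function")
  vapply(tau, function(t) {
    if (t < 0) return(0)
    g <- hazard(t)
    if (any(hazard(seq(0, max(t, 1e-12), length.out = 64L)) < 0) || g < 0)
      stop("hazard must be nonnegative")
    ch <- if (t == 0) 0 else quad(hazard, 0, t)
    g * exp(-ch)
  }, numeric(1))
}

#' Raw moments of the interdivision-time law
#'
#' @inheritParams idt_density
#' @return A list with `mean`, `m2` (second raw moment) and `cv2`.
#' @keywords internal
idt_moments <- function(model) {
  stopifnot_idt(model)
  switch(model$family,
    exponential = list(mean = model$mean, m2 = 2 * model$mean^2, cv2 = 1),
    gamma = list(mean = model$mean,
                 m2 = model$mean^2 * (1 + 1 / model$shape),
                 cv2 = 1 / model$shape),
    lognormal = list(mean = model$mean,
                     m2 = model$mean^2 * (1 + model$cv^2),
                     cv2 = model$cv^2),
    deterministic = list(mean = model$mean, m2 = model$mean^2, cv2 = 0),
    custom = {
      m2 <- quad(function(t) t^2 * model$density(t), 0, Inf)
      list(mean = model$mean, m2 = m2, cv2 = m2 / model$mean^2 - 1)
    })
}

#' Laplace transform of the interdivision-time density
#'
#' \eqn{L(s) = \int_0^\infty e^{-s\tau_d}\phi(\tau_d)\,d\tau_d}, used by the
#' Euler-Lotka solver. Closed forms are used where available.
#' @inheritParams idt_density
#' @param s Transform argument (1/time).
#' @return Transform values.
#' @export
idt_laplace <- function(model, s) {
  stopifnot_idt(model)
  switch(model$family,
    exponential = model$rate / (model$rate + s),
    gamma = (model$rate / (model$rate + s))^model$shape,
    deterministic = exp(-s * model$mean),
    quad(function(t) exp(-s * t) * idt_density(model, t), 0, Inf))
}

#' Upper truncation age
#'
#' The \eqn{(1 - p)} quantile of \eqn{\phi}; ages beyond it carry negligible
#' probability under every density of the framework (exponential suppression
#' for the population densities, survival decay for the lineage ones).
#' @inheritParams idt_density
#' @param p Tail mass to discard (default `1e-10`).
#' @return The truncation age.
#' @export
idt_tau_max <- function(model, p = 1e-10) {
  if (model$family == "deterministic") return(model$mean)
  idt_quantile(model, 1 - p)
}
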