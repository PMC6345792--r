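#' Reaction specifications
#'
#' Building blocks for [reaction_network()]. `mass_action()` specifies a
#' reaction with propensity \eqn{k \prod_i x_i^{(\nu_i^-)}} (falling
#' factorials for integer states, plain powers for the rate equations);
#' `hill_repression()` a zeroth-order production with transcriptional
#' repression \eqn{h(p) = k_0 / (1 + (p/K)^n)} read off a named species;
#' `burst_production()` a zeroth-order reaction firing at rate \eqn{k_0}
#' that produces a geometrically distributed burst of molecules on one
#' species, with burst-size distribution
#' \eqn{P(m) = \frac{1}{1+b}\left(\frac{b}{1+b}\right)^m}, \eqn{m \ge 0},
#' mean \eqn{b} and \eqn{E[m^2] = b(2b+1)}.
#'
#' @param rate Rate constant (1/time; for mass action, per reactant
#'   combination).
#' @param reactants,products Named integer vectors of stoichiometric
#'   coefficients over species names (absent species are 0).
#' @param K,n Hill dissociation constant and exponent.
#' @param species Name of the regulating (hill) or produced (burst) species.
#' @param b Mean burst size.
#' @return A reaction specification list, for use in [reaction_network()].
#' @name reaction_specs
NULL

#' @rdname reaction_specs
#' @export
mass_action <- function(rate, reactants = c(), products = c()) {
  stopifnot(is.numeric(rate), rate >= 0)
  list(type = "mass_action", rate = rate,
       reactants = reactants, products = products)
}

#' @rdname reaction_specs
#' @export
hill_repression <- function(rate, K, n = 4, species, products) {
  stopifnot(rate >= 0, K > 0, n > 0)
  list(type = "hill", rate = rate, K = K, n = n, species = species,
       reactants = c(), products = products)
}

#' @rdname reaction_specs
#' @export
burst_production <- function(rate, b, species) {
  stopifnot(rate >= 0, b > 0)
  pr <- stats::setNames(1L, species)
  list(type = "burst", rate = rate, b = b, species = species,
       reactants = c(), products = pr)
}

#' Intracellular reaction network
#'
#' Assembles species and reactions into a network object carrying the net
#' stoichiometric matrix and propensity specifications. Networks are the
#' chemistry input of the age-resolved moment solver
#' ([solve_cyclostationary()]) and of the agent-based simulator
#' ([simulate_population()]).
#'
#' @param species Character vector of species names (ordered).
#' @param reactions List of reactions built with [mass_action()],
#'   [hill_repression()] or [burst_production()].
#' @return An object of class `"reaction_network"`.
#' @examples
#' net <- reaction_network("Protein",
#'   list(burst_production(rate = 10, b = 10, species = "Protein")))
#' propensities(net, c(Protein = 5))
#' @export
reaction_network <- function(species, reactions) {
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species), is.list(reactions))
  n <- length(species)
  stoich <- function(v) {
    out <- stats::setNames(numeric(n), species)
    if (length(v)) {
      bad <- setdiff(names(v), species)
      if (length(bad)) stop("unknown species in reaction: ",
                            paste(bad, collapse = ", "))
      out[names(v)] <- v
    }
    out
  }
  reactions <- lapply(reactions, function(r) {
    if (!is.list(r) || is.null(r$type)) stop("malformed reaction spec")
    r$nu_minus <- stoich(r$reactants)
    r$nu <- stoich(r$products) - r$nu_minus
    if (any(r$nu != round(r$nu))) stop("stoichiometry must be integer-valued")
    if (r$type == "hill" && !(r$species %in% species))
      stop("hill regulator species not in network: ", r$species)
    r
  })
  structure(list(species = species, n_species = n, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", x$n_species, "species (",
      paste(x$species, collapse = ", "), "),",
      length(x$reactions), "reactions\n")
  for (r in x$reactions) {
    lhs <- paste0(ifelse(r$nu_minus > 0,
                         paste0(r$nu_minus, " ", x$species), ""), collapse = "")
    cat("  -", r$type, " nu = (", paste(r$nu, collapse = ", "), ")\n")
  }
  invisible(x)
}

#' Reaction propensities
#'
#' Evaluates the propensity vector \eqn{w_r(x)} at a state `x`. With
#' `discrete = TRUE` (integer molecule counts, as in the stochastic
#' simulation) mass-action propensities use falling factorials
#' \eqn{x(x-1)\cdots}; with `discrete = FALSE` (the default, used by the
#' rate equations and the linear noise approximation) plain powers of the
#' mean are used. Burst production contributes its firing rate \eqn{k_0}
#' (the burst size enters the drift and diffusion separately, see
#' [jacobian_at()] and [diffusion_at()]).
#'
#' @param net A [reaction_network()].
#' @param x Named or ordered numeric state vector (nonnegative).
#' @param discrete Use falling-factorial combinatorics for mass action.
#' @return Numeric vector of rates, one per reaction.
#' @export
propensities <- function(net, x, discrete = FALSE) {
  x <- as_state(net, x)
  if (any(x < 0)) stop("molecule counts must be nonnegative")
  vapply(net$reactions, function(r) prop_one(r, x, discrete), numeric(1))
}

as_state <- function(net, x) {
  if (!is.null(names(x))) {
    miss <- setdiff(net$species, names(x))
    if (length(miss)) stop("state misses species: ", paste(miss, collapse = ", "))
    x <- x[net$species]
  }
  if (length(x) != net$n_species) stop("state has wrong length")
  as.numeric(x)
}

prop_one <- function(r, x, discrete = FALSE) {
  switch(r$type,
    mass_action = {
      w <- r$rate
      for (i in which(r$nu_minus > 0)) {
        k <- r$nu_minus[i]
        w <- w * if (discrete) prod(pmax(x[i] - seq_len(k) + 1, 0)) else x[i]^k
      }
      w
    },
    hill = {
      p <- x[match(r$species, names(r$nu))]
      r$rate / (1 + (p / r$K)^r$n)
    },
    burst = r$rate)
}

#' Drift, Jacobian and diffusion of a network at a mean state
#'
#' The linear noise approximation characterises the age-resolved moments by
#' the drift \eqn{\sum_r \nu_r w_r(E[x|\tau])}, the Jacobian
#' \eqn{\mathcal{J}_{ij} = \sum_r \nu_{ir}\,\partial w_r/\partial x_j} and
#' the diffusion matrix
#' \eqn{\mathcal{D}_{ij} = \sum_r \nu_{ir}\nu_{jr} w_r}, all evaluated at
#' the mean. A burst-production reaction enters the drift with its mean
#' burst size \eqn{b} (production \eqn{k_0 b}) and the diffusion with the
#' full second moment of the geometric burst,
#' \eqn{k_0 E[m^2] = k_0\, b(2b+1)}.
#'
#' @inheritParams propensities
#' @param mean Mean state (nonnegative reals).
#' @return `drift_at`: numeric vector; `jacobian_at`, `diffusion_at`:
#'   \eqn{n \times n} matrices (1/time and counts\eqn{^2}/time).
#' @export
drift_at <- function(net, mean) {
  mean <- as_state(net, mean)
  d <- numeric(net$n_species)
  for (r in net$reactions) d <- d + nu_drift(r) * prop_one(r, mean)
  unname(d)
}

nu_drift <- function(r) {
  if (r$type == "burst") r$nu * r$b else r$nu
}

#' @rdname drift_at
#' @export
jacobian_at <- function(net, mean) {
  mean <- as_state(net, mean)
  n <- net$n_species
  J <- matrix(0, n, n, dimnames = list(NULL, NULL))
  for (r in net$reactions) {
    grad <- numeric(n)
    if (r$type == "mass_action") {
      for (j in which(r$nu_minus > 0)) {
        k <- r$nu_minus[j]
        others <- prop_one(r, `[<-`(mean, j, 1), FALSE) # rate * rest at x_j = 1
        grad[j] <- others * k * mean[j]^(k - 1)
      }
    } else if (r$type == "hill") {
      j <- match(r$species, names(r$nu))
      p <- mean[j]
      u <- (p / r$K)^r$n
      grad[j] <- if (p > 0) -r$rate * r$n * u / p / (1 + u)^2 else 0
    } # burst: propensity constant, zero gradient
    J <- J + outer(nu_drift(r), grad)
  }
  unname(J)
}

#' @rdname drift_at
#' @export
diffusion_at <- function(net, mean) {
  mean <- as_state(net, mean)
  n <- net$n_species
  D <- matrix(0, n, n)
  for (r in net$reactions) {
    w <- prop_one(r, mean)
    if (r$type == "burst") {
      i <- match(r$species, names(r$nu))
      D[i, i] <- D[i, i] + w * r$b * (2 * r$b + 1) # k0 E[m^2], geometric burst
    } else {
      D <- D + tcrossprod(r$nu) * w
    }
  }
  D
}

#' Is every propensity affine in the molecule numbers?
#'
#' Linear (affine) networks admit exact moment equations that coincide with
#' the linear noise approximation, and an algebraic snapshot decomposition
#' ([linear_exact()]).
#' @inheritParams propensities
#' @return Logical.
#' @export
is_linear_network <- function(net) {
  all(vapply(net$reactions, function(r) {
    r$type != "hill" && sum(r$nu_minus) <= 1
  }, logical(1)))
}

#' Duplicate a network into a two-reporter system
#'
#' Creates an additional, identical and non-interacting copy of every
#' species and reaction, modelling a dual-reporter experiment: both copies
#' share the cell's division timing (a property of the solver/simulator, not
#' of the network) but fire reactions independently. Species of copy `i`
#' are suffixed `"_i"`.
#'
#' @inheritParams propensities
#' @return A [reaction_network()] with twice the species.
#' @export
duplicate_reporters <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  rename <- function(v, sfx) {
    if (!length(v)) return(stats::setNames(numeric(0), character(0)))
    stats::setNames(v, paste0(names(v), sfx))
  }
  copies <- lapply(c("_1", "_2"), function(sfx) {
    lapply(net$reactions, function(r) {
      r$reactants <- rename(r$nu_minus[r$nu_minus != 0], sfx)
      r$products <- rename((r$nu + r$nu_minus)[(r$nu + r$nu_minus) != 0], sfx)
      if (r$type %in% c("hill", "burst")) r$species <- paste0(r$species, sfx)
      r[c("type", "rate", "K", "n", "b", "species", "reactants", "products")]
    })
  })
  reaction_network(paste0(rep(net$species, 2), rep(c("_1", "_2"),
                                                   each = net$n_species)),
                   lapply(c(copies[[1]], copies[[2]]),
                          function(r) r[!vapply(r, is.null, logical(1))]))
}

#' Built-in model networks
#'
#' Presets used throughout the package:
#' \describe{
#'   \item{`bursty_reporter`}{a single stable protein produced in geometric
#'     bursts at rate `k0` with mean burst size `b`. When built from
#'     `(k0, km, ks)` the burst approximation `b = ks/km` of fast mRNA
#'     turnover is applied.}
#'   \item{`transcription_translation`}{mRNA synthesis (`k0`) and decay
#'     (`km`), translation (`ks`); the protein is stable and diluted only by
#'     division.}
#'   \item{`negative_feedback`}{as above, but transcription is repressed by
#'     the protein through a Hill function
#'     \eqn{h(p) = k_0/(1+(p/K)^n)}.}
#' }
#'
#' @param name Preset id.
#' @param k0 Transcription / burst firing rate.
#' @param b Mean burst size (`bursty_reporter`).
#' @param km mRNA degradation rate.
#' @param ks Translation rate.
#' @param K,n Hill dissociation constant and exponent (`negative_feedback`).
#' @return A [reaction_network()].
#' @export
builtin_network <- function(name = c("bursty_reporter",
                                     "transcription_translation",
                                     "negative_feedback"),
                            k0 = 10, b = NULL, km = 1, ks = 10,
                            K = 100, n = 4) {
  name <- match.arg(name)
  switch(name,
    bursty_reporter = {
      if (is.null(b)) b <- ks / km # burst approximation of fast mRNA turnover
      reaction_network("Protein",
        list(burst_production(rate = k0, b = b, species = "Protein")))
    },
    transcription_translation = reaction_network(c("mRNA", "Protein"), list(
      mass_action(k0, products = c(mRNA = 1)),
      mass_action(km, reactants = c(mRNA = 1)),
      mass_action(ks, reactants = c(mRNA = 1),
                  products = c(mRNA = 1, Protein = 1)))),
    negative_feedback = reaction_network(c("mRNA", "Protein"), list(
      hill_repression(k0, K = K, n = n, species = "Protein",
                      products = c(mRNA = 1)),
      mass_action(km, reactants = c(mRNA = 1)),
      mass_action(ks, reactants = c(mRNA = 1),
                  products = c(mRNA = 1, Protein = 1)))))
}

# Flatten a network into the plain-vector form consumed by the C++ simulator.
net_to_cpp <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  R <- length(net$reactions)
  n <- net$n_species
  nu <- matrix(0L, n, R)
  order_m <- matrix(0L, n, R)
  type <- integer(R); rate <- numeric(R)
  hillK <- numeric(R); hilln <- numeric(R); hill_s <- integer(R)
  burst_b <- numeric(R); burst_s <- integer(R)
  for (r in seq_len(R)) {
    rr <- net$reactions[[r]]
    nu[, r] <- as.integer(rr$nu)
    order_m[, r] <- as.integer(rr$nu_minus)
    rate[r] <- rr$rate
    type[r] <- switch(rr$type, mass_action = 0L, hill = 1L, burst = 2L)
    hill_s[r] <- burst_s[r] <- -1L
    if (rr$type == "hill") {
      hillK[r] <- rr$K; hilln[r] <- rr$n
      hill_s[r] <- match(rr$species, net$species) - 1L
    }
    if (rr$type == "burst") {
      burst_b[r] <- rr$b
      burst_s[r] <- match(rr$species, net$species) - 1L
    }
  }
  list(n = n, R = R, nu = nu, order = order_m, type = type, rate = rate,
       hillK = hillK, hilln = hilln, hill_s = hill_s,
       burst_b = burst_b, burst_s = burst_s)
}
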