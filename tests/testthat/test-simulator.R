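test_that("SSA leaves counts unchanged over zero duration", {
  net <- builtin_network("bursty_reporter", k0 = 10, b = 10)
  expect_equal(ssa_within_cell(net, c(Protein = 7), 0), c(Protein = 7))
})

test_that("SSA reproduces first-order decay and compound-Poisson bursts", {
  death <- reaction_network("X", list(mass_action(1, reactants = c(X = 1))))
  set.seed(101)
  survivors <- replicate(200, ssa_within_cell(death, c(X = 1000), 1))
  se <- stats::sd(survivors) / sqrt(length(survivors))
  expect_lt(abs(mean(survivors) - 1000 * exp(-1)), 3 * se)

  # burst production: increment over dt has mean k0 b dt and
  # variance k0 b (2b+1) dt
  k0 <- 5; b <- 4; dt <- 1
  burst <- builtin_network("bursty_reporter", k0 = k0, b = b)
  set.seed(102)
  inc <- replicate(1e4, ssa_within_cell(burst, c(Protein = 0), dt))
  expect_lt(abs(mean(inc) - k0 * b * dt),
            3 * stats::sd(inc) / sqrt(length(inc)))
  v <- stats::var(inc)
  se_v <- v * sqrt(2 / (length(inc) - 1)) # normal-approx SE of the variance
  expect_lt(abs(v - k0 * b * (2 * b + 1) * dt), 5 * se_v)
})

test_that("division conserves molecules and splits them symmetrically", {
  set.seed(103)
  for (i in 1:50) {
    mother <- c(10, 4)
    d <- divide_cell(mother)
    expect_equal(d[[1]] + d[[2]], mother)
  }
  draws <- t(replicate(1e4, divide_cell(c(100, 40))[[1]]))
  expect_lt(abs(mean(draws[, 1]) - 50), 3 * sqrt(100 / 4 / 1e4))
  expect_lt(abs(stats::var(draws[, 1]) - 25), 5 * 25 * sqrt(2 / 1e4))
  expect_lt(abs(stats::var(draws[, 2]) - 10), 5 * 10 * sqrt(2 / 1e4))
})

test_that("deterministic interdivision times give synchronous doubling", {
  net <- builtin_network("bursty_reporter", k0 = 10, b = 10)
  model <- interdivision_model("deterministic", mean = 1)
  snap <- simulate_population(net, model, t_final = 2.9, seed = 1)
  expect_equal(nrow(snap), 4)
  expect_true(all(snap$depth == 2))
  expect_equal(snap$age, rep(0.9, 4), tolerance = 1e-12)
})

test_that("simulations are reproducible under a fixed seed", {
  net <- duplicate_reporters(builtin_network("bursty_reporter", k0 = 10,
                                             b = 10))
  model <- interdivision_model("lognormal", mean = 1, cv = 0.5)
  s1 <- simulate_population(net, model, t_final = 6, mode = "constant_N",
                            n_max = 200, seed = 7)
  s2 <- simulate_population(net, model, t_final = 6, mode = "constant_N",
                            n_max = 200, seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  l1 <- simulate_lineage(net, model, n_divisions = 50, seed = 8)
  l2 <- simulate_lineage(net, model, n_divisions = 50, seed = 8)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
})

test_that("custom interdivision laws are rejected by the simulator", {
  net <- builtin_network("bursty_reporter")
  m <- interdivision_model("custom", density = function(t) exp(-t))
  expect_error(simulate_population(net, m, t_final = 1), "custom")
})

test_that("lineage traces sample the single-cell interdivision law", {
  net <- builtin_network("bursty_reporter", k0 = 10, b = 10)
  model <- interdivision_model("gamma", mean = 1, cv = 0.5)
  tr <- simulate_lineage(net, model, n_divisions = 2000, seed = 5)
  divs <- diff(attr(tr, "division_times"))
  se <- stats::sd(divs) / sqrt(length(divs))
  expect_lt(abs(mean(divs) - 1), 3.5 * se)
  # ages reset at divisions: age minima occur right after division times
  expect_lt(min(tr$age), attr(tr, "division_times")[1])
})

test_that("two-reporter estimators satisfy their algebraic identities", {
  set.seed(104)
  n <- 2000
  x <- rpois(n, 50)
  df <- data.frame(age = runif(n), Protein_1 = x, Protein_2 = x)
  est <- estimate_decomposition(df, n_boot = 0)$pooled
  # identical reporters: all variability is extrinsic
  expect_equal(est$sigma_int, 0)
  expect_equal(est$sigma_ext, mean(x^2) - mean(x)^2)

  # independently permuted reporters: no shared-history covariance
  df2 <- data.frame(age = runif(n), Protein_1 = rpois(n, 50),
                    Protein_2 = rpois(n, 50))
  est2 <- estimate_decomposition(df2, n_boot = 200, seed = 1)$pooled
  expect_lt(abs(est2$sigma_ext), 3 * est2$se_sigma_ext)
  # label exchange leaves the estimators unchanged
  df3 <- data.frame(age = df2$age, Protein_1 = df2$Protein_2,
                    Protein_2 = df2$Protein_1)
  est3 <- estimate_decomposition(df3, n_boot = 0)$pooled
  expect_equal(est3$sigma_int, est2$sigma_int)
  expect_equal(est3$sigma_ext, est2$sigma_ext)
})

test_that("age-binned estimators use equal-count bins", {
  set.seed(105)
  n <- 1000
  df <- data.frame(age = runif(n), Protein_1 = rpois(n, 20),
                   Protein_2 = rpois(n, 20))
  est <- estimate_decomposition(df, age_bins = 10, n_boot = 0)
  expect_equal(nrow(est$by_age), 10)
  expect_true(all(diff(est$by_age$age) > 0))
  expect_error(estimate_decomposition(df[1:5, ], age_bins = 5, n_boot = 0),
               "2 cells per age bin")
  expect_error(estimate_decomposition(data.frame(age = 1:10, X = 1:10)),
               "dual-reporter")
})

test_that("memoryless division reproduces the growth-limited snapshot mean", {
  # constant age-independent division rate k: lambda = k
  k0 <- 10; b <- 10
  net <- duplicate_reporters(builtin_network("bursty_reporter", k0 = k0,
                                             b = b))
  model <- interdivision_model("exponential", mean = 1)
  snap <- simulate_population(net, model, t_final = 22, mode = "constant_N",
                              n_max = 4000, seed = 12)
  est <- estimate_decomposition(snap, n_boot = 100, seed = 2)$pooled
  expect_lt(abs(est$mean - k0 * b / 1), 3 * est$se_mean)
})

test_that("simulation tables serialise with their metadata sidecar", {
  net <- builtin_network("bursty_reporter")
  model <- interdivision_model("gamma", mean = 1, cv = 0.5)
  snap <- simulate_population(net, model, t_final = 3, seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_simulation(snap, tmp)
  expect_true(file.exists(tmp))
  meta <- yaml::read_yaml(paste0(tmp, ".meta.yaml"))
  expect_equal(meta$n_rows, nrow(snap))
  expect_equal(meta$seed, 3)
  back <- utils::read.delim(tmp)
  expect_equal(nrow(back), nrow(snap))
  unlink(c(tmp, paste0(tmp, ".meta.yaml")))
})
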