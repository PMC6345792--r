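test_that("propagation of the bursty reporter has linear moment profiles", {
  net <- builtin_network("bursty_reporter", k0 = 1, b = 100)
  grid <- seq(0, 2, length.out = 51)
  st <- list(mean = 50, sigma_int = matrix(500, 1, 1),
             sigma_ext = matrix(120, 1, 1))
  prof <- propagate(net, st, grid)
  # production k0 b = 100 per unit age
  expect_equal(prof$mean[, 1], 100 * grid + 50, tolerance = 1e-8)
  # intrinsic variance grows at b(2b+1) k0 = 20100; extrinsic is transported
  expect_equal(prof$sint[, 1], 500 + 20100 * grid, tolerance = 1e-8)
  expect_equal(prof$sext[, 1], rep(120, length(grid)), tolerance = 1e-10)
})

test_that("division averages reduce to point evaluation for deterministic division", {
  net <- builtin_network("bursty_reporter", k0 = 1, b = 100)
  ps <- population_structure(interdivision_model("deterministic", mean = 1))
  grid <- age_grid(ps, 100)
  st <- list(mean = 50, sigma_int = matrix(0, 1, 1),
             sigma_ext = matrix(0, 1, 1))
  prof <- propagate(net, st, grid)
  da <- division_averages(prof, ps, "population")
  expect_equal(da$mean, 150, tolerance = 1e-7)          # 100 * 1 + 50
  expect_equal(da$sint[1, 1], 20100, tolerance = 1e-6)
  expect_equal(da$cov_mean[1, 1], 0)                    # no cell cycle noise
})

test_that("a constant mean profile carries no cell-cycle covariance", {
  ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
  grid <- age_grid(ps, 200)
  prof <- list(grid = grid, mean = matrix(7, length(grid), 1),
               sint = matrix(3, length(grid), 1),
               sext = matrix(1, length(grid), 1), n = 1L)
  da <- division_averages(prof, ps, "population")
  expect_equal(da$cov_mean[1, 1], 0, tolerance = 1e-10)
  expect_equal(da$mean, 7, tolerance = 1e-8)
})

test_that("binomial birth update halves means and splits noise sources", {
  da <- list(mean = c(10, 4), sint = diag(c(8, 2)), sext = diag(c(4, 1)),
             cov_mean = matrix(c(2, 1, 1, 2), 2))
  b <- birth_update(da)
  expect_equal(b$mean, c(5, 2))
  # 4 Sigma_int(0) = E[Sigma_int] + E[diag(mean)]
  expect_equal(b$sigma_int, (diag(c(8, 2)) + diag(c(10, 4))) / 4)
  # 4 Sigma_ext(0) = E[Sigma_ext] + Cov_w[mean]
  expect_equal(b$sigma_ext, (diag(c(4, 1)) + matrix(c(2, 1, 1, 2), 2)) / 4)
  # custom kernels must still split means equally
  expect_error(birth_update(da, kernel = list(cov_b = function(m) diag(m) / 4,
                                              mean_fraction = 0.6)),
               "equally")
  # a custom kernel reproducing the binomial covariance gives the same state
  b2 <- birth_update(da, kernel = list(cov_b = function(m) diag(m) / 4))
  expect_equal(b2, b)
})

test_that("cyclostationary birth state matches the bursty closed forms", {
  k0 <- 1; b <- 100
  net <- builtin_network("bursty_reporter", k0 = k0, b = b)
  ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
  am <- solve_cyclostationary(net, ps, "population", grid_n = 200)
  expect_true(am$converged)
  Erho <- ps$mean_rho
  expect_equal(am$birth$mean, k0 * b * Erho, tolerance = 1e-6)
  expect_equal(am$birth$sigma_int[1, 1], b * (2 * b + 3) * k0 * Erho / 3,
               tolerance = 1e-6)
  expect_equal(am$birth$sigma_ext[1, 1],
               b^2 * k0^2 * Erho^2 * ps$cv2_rho / 3, tolerance = 1e-6)
})

test_that("means double over the cycle and covariances stay PSD", {
  net <- builtin_network("transcription_translation", k0 = 10, km = 1, ks = 10)
  for (nm in c("gamma_2", "lognormal_05")) {
    ps <- population_structure(unit_mean_models()[[nm]])
    for (ens in c("population", "lineage")) {
      am <- solve_cyclostationary(net, ps, ens, grid_n = 200)
      da <- am$division
      expect_lt(max(abs(am$birth$mean - da$mean / 2)),
                1e-6 * max(abs(am$birth$mean)))
      idx <- round(seq(1, length(am$grid), length.out = 20))
      for (k in idx) {
        expect_gte(min(eigen(am$sigma_int[k, , ], symmetric = TRUE)$values),
                   -1e-8 * max(am$sigma_int[k, , ]))
        expect_gte(min(eigen(am$sigma_ext[k, , ], symmetric = TRUE)$values),
                   -1e-8 * max(abs(am$sigma_ext[k, , ])))
      }
    }
  }
})

test_that("lineage profiles follow the phi-substituted closed form", {
  k0 <- 1; b <- 100
  net <- builtin_network("bursty_reporter", k0 = k0, b = b)
  ps <- population_structure(interdivision_model("lognormal", mean = 1,
                                                 cv = 0.5))
  am <- solve_cyclostationary(net, ps, "lineage", grid_n = 200)
  expect_equal(am$mean[, 1], k0 * b * (as.numeric(am$grid) + ps$mean_phi),
               tolerance = 1e-6)
})

test_that("a silent network has the zero fixed point", {
  net <- reaction_network("X", list(mass_action(0, products = c(X = 1))))
  ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
  am <- solve_cyclostationary(net, ps, "population", grid_n = 100)
  expect_equal(max(abs(am$mean)), 0)
  expect_equal(max(abs(am$sigma_int)), 0)
})

test_that("non-convergence raises an informative error", {
  net <- builtin_network("bursty_reporter", k0 = 1, b = 100)
  ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
  expect_error(solve_cyclostationary(net, ps, max_iter = 2L, grid_n = 100),
               "did not converge")
})

test_that("age-moment tables flatten the per-age moments", {
  net <- builtin_network("bursty_reporter", k0 = 1, b = 100)
  ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
  am <- solve_cyclostationary(net, ps, grid_n = 100)
  df <- as.data.frame(am)
  expect_named(df, c("age", "mean_Protein", "sint_Protein_Protein",
                     "sext_Protein_Protein"))
  expect_equal(nrow(df), length(am$grid))
  expect_equal(df$mean_Protein, unname(am$mean[, 1]))
})
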