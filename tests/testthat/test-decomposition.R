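test_that("bursty closed forms reproduce hand-computed values", {
  ps_exp <- population_structure(interdivision_model("exponential", mean = 1))
  # age-resolved: at birth, extrinsic noise is CV2_rho / 3
  cf0 <- closed_form_bursty(1, 100, ps_exp, "population", tau = 0)
  expect_equal(cf0$cv2_ext, ps_exp$cv2_rho / 3)
  # k0 = 1, b = 100, E_rho = 1/2: mean at birth = 50
  expect_equal(cf0$mean, 50)
  # deterministic T = 1: unknown-age snapshot mean k0 b / ln 2
  ps_det <- population_structure(interdivision_model("deterministic", mean = 1))
  cfd <- closed_form_bursty(10, 10, ps_det, "population")
  expect_equal(cfd$mean, 100 / log(2), tolerance = 1e-10)
})

test_that("unknown-age closed forms agree with the exact linear solve", {
  k0 <- 10; b <- 10
  net <- builtin_network("bursty_reporter", k0 = k0, b = b)
  for (nm in c("gamma_2", "lognormal_05")) {
    ps <- population_structure(unit_mean_models()[[nm]])
    for (ens in c("population", "lineage")) {
      cf <- closed_form_bursty(k0, b, ps, ens)
      le <- linear_exact(net, ps, ens, grid_n = 300)
      expect_equal(unname(le$mean), cf$mean, tolerance = 1e-6)
      expect_equal(unname(le$cv2_int), cf$cv2_int, tolerance = 1e-5)
      expect_equal(unname(le$cv2_cc), cf$cv2_cc, tolerance = 1e-5)
      expect_equal(unname(le$cv2_age), cf$cv2_age, tolerance = 1e-5)
    }
  }
  # snapshot mean is growth-limited: k0 b / lambda
  ps <- population_structure(unit_mean_models()$gamma_2)
  expect_equal(closed_form_bursty(k0, b, ps, "population")$mean,
               k0 * b / ps$lambda)
  # lineage mean depends on age and interdivision time
  expect_equal(closed_form_bursty(k0, b, ps, "lineage")$mean,
               b * k0 * (ps$mean_phi + ps$mean_pi))
})

test_that("decomposition components add up and stay PSD", {
  net <- builtin_network("transcription_translation", k0 = 10, km = 1, ks = 10)
  ps <- population_structure(interdivision_model("lognormal", mean = 1,
                                                 cv = 0.5))
  dec <- age_average(solve_cyclostationary(net, ps, "population",
                                           grid_n = 300))
  expect_equal(dec$sigma_tot, dec$sigma_int + dec$sigma_cc + dec$sigma_age)
  expect_equal(dec$sigma_ext, dec$sigma_cc + dec$sigma_age)
  for (S in list(dec$sigma_int, dec$sigma_cc, dec$sigma_age)) {
    expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-8 * max(S))
  }
  expect_equal(unname(dec$cv2_tot),
               unname(dec$cv2_int + dec$cv2_cc + dec$cv2_age))
  expect_error(age_average(structure(list(converged = FALSE),
                                     class = "age_moments")),
               "not converged")
})

test_that("intrinsic-noise peak age matches numerical maximisation", {
  # no interior maximum at or below the onset burst size
  expect_equal(intrinsic_peak_age(1.5), 0)
  expect_equal(intrinsic_peak_age(0.5), 0)
  expect_equal(intrinsic_peak_age(100), 197 / 603)
  expect_equal(intrinsic_peak_age(1e9), 1 / 3, tolerance = 1e-8)
  # cross-check against direct maximisation of the age-resolved formula
  ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
  for (b in c(2, 10, 100)) {
    f <- function(tau) closed_form_bursty(1, b, ps, "population",
                                          tau = tau)$cv2_int
    opt <- stats::optimize(f, c(0, 3 * ps$mean_rho), maximum = TRUE,
                           tol = 1e-10)
    expect_equal(opt$maximum / ps$mean_rho, intrinsic_peak_age(b),
                 tolerance = 1e-4)
  }
})

test_that("linear_exact rejects nonlinear networks", {
  fb <- builtin_network("negative_feedback")
  ps <- population_structure(interdivision_model("gamma", mean = 1, cv = 0.5))
  expect_error(linear_exact(fb, ps), "non-affine")
})

test_that("population means are bounded by lineage means (bursty reporter)", {
  for (nm in c("gamma_05", "gamma_2", "gamma_4", "lognormal_025",
               "lognormal_1")) {
    ps <- population_structure(unit_mean_models()[[nm]])
    expect_lt(closed_form_bursty(10, 10, ps, "population")$mean,
              closed_form_bursty(10, 10, ps, "lineage")$mean)
  }
})

test_that("feedback sweep recovers the open-loop limit at weak feedback", {
  ps <- population_structure(interdivision_model("lognormal", mean = 1,
                                                 cv = 0.5))
  # at K -> infinity the Hill repression is never engaged and the circuit
  # reduces exactly to unregulated transcription-translation
  sw <- sweep_feedback(K_values = 1e8, cv_values = 0.5,
                       ensembles = "population", grid_n = 300)
  tt <- builtin_network("transcription_translation", k0 = 10, km = 1, ks = 10)
  ref <- as.data.frame(linear_exact(tt, ps, "population", grid_n = 300))
  expect_equal(sw$mean, ref$mean, tolerance = 1e-5)
  expect_equal(sw$cv2_int, ref$cv2_int, tolerance = 1e-4)
  expect_equal(sw$cv2_ext, ref$cv2_ext, tolerance = 1e-4)
  expect_true(all(sw$status == "ok"))
})

test_that("solver failures are recorded per sweep point, not fatal", {
  sw <- sweep_feedback(K_values = 100, cv_values = 0.5,
                       ensembles = "population", grid_n = 100, max_iter = 2L)
  expect_true(all(is.na(sw$mean)))
  expect_match(sw$status[1], "converge")
})

test_that("protein means show opposite cell-cycle sensitivities under feedback", {
  sw <- sweep_feedback(K_values = c(50, 200), cv_values = c(0.3, 0.8),
                       ensembles = c("population", "lineage"), grid_n = 200)
  expect_true(all(sw$status == "ok"))
  prot <- sw[sw$species == "Protein", ]
  for (K in c(50, 200)) {
    pop <- prot[prot$ensemble == "population" & prot$K == K, ]
    lin <- prot[prot$ensemble == "lineage" & prot$K == K, ]
    # snapshot protein levels fall with cell-cycle noise, lineage levels rise
    expect_lt(pop$mean[pop$cv_phi == 0.8], pop$mean[pop$cv_phi == 0.3])
    expect_gt(lin$mean[lin$cv_phi == 0.8], lin$mean[lin$cv_phi == 0.3])
  }
})

test_that("noise-minimising feedback strengths differ between ensembles", {
  opts <- lapply(c("population", "lineage"), function(ens)
    optimal_feedback("cv2_int", species = "Protein", cv_phi = 0.5,
                     ensemble = ens, K_range = c(30, 500), n_grid = 5,
                     tol = 1e-2, grid_n = 120))
  for (o in opts) {
    expect_gt(o$K_opt, 30 * 1.05)        # interior optimum
    expect_lt(o$K_opt, 500 / 1.05)
    expect_gt(o$value, 0)
  }
  # the two ensembles are minimised by different feedback strengths
  expect_gt(abs(log(opts[[1]]$K_opt / opts[[2]]$K_opt)), 0.05)
})
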