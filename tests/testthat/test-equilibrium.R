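test_that("fraction_bound matches the mass-action root-finder and known values", {
  # printed-condition value: 50 uM protein, 5x peptide, K_D 45 uM
  expect_equal(fraction_bound(50, 250, 45), 0.8227, tolerance = 1e-4)
  expect_equal(fraction_bound(50, 0, 45), 0)
  expect_equal(fraction_bound(10, 100, 45), fraction_bound_oracle(10, 100, 45),
               tolerance = 1e-12)
  expect_equal(round(fraction_bound(10, 100, 45), 3), 0.675)

  set.seed(11)
  for (i in 1:200) {
    p <- runif(1, 0.1, 1000); l <- runif(1, 0.1, 1000)
    kd <- runif(1, 0.1, 1000)
    expect_lt(abs(fraction_bound(p, l, kd) - fraction_bound_oracle(p, l, kd)),
              1e-9)
  }
})

test_that("fraction_bound is monotone in ligand and in kd, and bounded", {
  l_grid <- seq(0, 500, by = 10)
  kd_grid <- c(1, 5, 20, 45, 104, 500)
  for (kd in kd_grid) {
    f <- fraction_bound(50, l_grid, kd)
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= 0 & f <= pmin(1, l_grid / 50)))
  }
  for (l in c(10, 100, 400)) {
    f <- vapply(kd_grid, function(kd) fraction_bound(50, l, kd), 0)
    expect_true(all(diff(f) < 0))
  }
})

test_that("fraction_bound and predicted_response reject invalid parameters", {
  expect_error(fraction_bound(0, 10, 45), "protein_total")
  expect_error(fraction_bound(50, 10, 0), "kd")
  expect_error(fraction_bound(50, -1, 45), "ligand_total")
  expect_error(predicted_response(50, 10, 45, NaN), "response_max")
})

test_that("predicted_response scales fraction_bound and hits its limits", {
  expect_equal(predicted_response(50, 250, 45, 0.10),
               0.10 * fraction_bound_oracle(50, 250, 45), tolerance = 1e-9)
  expect_equal(predicted_response(50, 0, 45, 0.10), 0)
  # stoichiometric limit: kd -> 0 with excess ligand saturates the response
  expect_equal(predicted_response(50, 100, 1e-9, 0.10), 0.10,
               tolerance = 1e-6)
})

test_that("titration_series enforces its invariants", {
  expect_error(titration_series(c(0, 0, 10), c(0, 1, 2), 50), "distinct")
  expect_error(titration_series(c(0, 10), c(0, 1), -1), "positive")
  s <- titration_series(c(100, 0, 10), c(2, 0, 1), 50, label = "x")
  expect_equal(s$ligand_total, c(0, 10, 100))  # sorted
})

test_that("fit_kd recovers noiseless generator parameters to 1e-6 relative", {
  s <- gen_titration(kd = 104, response_max = 0.05, protein_total = 50,
                     ligand_grid = seq(0, 600, length.out = 8),
                     noise_sd = 0, seed = 1)
  f <- fit_kd(s)
  expect_true(f$converged)
  expect_equal(f$kd, 104, tolerance = 1e-6)
  expect_equal(f$response_max, 0.05, tolerance = 1e-6)
  expect_length(f$residuals, 8)
  expect_lt(max(abs(f$residuals)), 1e-12)
})

test_that("fit_kd rejects degenerate and too-short series", {
  flat <- titration_series(c(0, 10, 20), c(0.3, 0.3, 0.3), 50)
  expect_error(fit_kd(flat), "degenerate")
  short <- titration_series(c(0, 10), c(0, 0.1), 50)
  expect_error(fit_kd(short), ">= 3")
})

test_that("fit_kd is a consistent estimator with honest uncertainty", {
  kds <- ses <- numeric(100)
  for (i in 1:100) {
    s <- gen_titration(kd = 104, response_max = 0.05, protein_total = 50,
                       ligand_grid = seq(0, 600, length.out = 8),
                       noise_sd = 0.05 * 0.05, seed = 1000 + i)
    f <- fit_kd(s)
    kds[i] <- f$kd; ses[i] <- f$kd_stderr
  }
  expect_lt(abs(median(kds) - 104) / 104, 0.15)
  expect_gte(mean(abs(kds - 104) <= 2 * ses), 0.80)
})

test_that("apparent adaptor affinity follows the activated fraction", {
  # saturating peptide: apparent = intrinsic
  sat <- coupled_system(kd_activation = 45, kd_intrinsic = 9,
                        arrestin_total = 10, peptide_total = 1e7)
  expect_equal(as.numeric(apparent_adaptor_kd(sat)), 9, tolerance = 1e-5)
  # partial activation: scaled by the 1/f_act
  sys <- coupled_system(45, 9, 10, 100)
  kd_app <- apparent_adaptor_kd(sys)
  f_oracle <- fraction_bound_oracle(10, 100, 45)
  expect_equal(as.numeric(kd_app), 9 / f_oracle, tolerance = 1e-9)
  expect_equal(round(as.numeric(kd_app), 1), 13.3)
  expect_equal(attr(kd_app, "f_act"), f_oracle, tolerance = 1e-9)
  # no peptide: no activated protein, affinity undefined
  expect_error(apparent_adaptor_kd(coupled_system(45, 9, 10, 0)),
               "undefined affinity")
})

test_that("complex_from_kd and apparent_kd are exact inverses", {
  set.seed(21)
  for (i in 1:200) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100); kd <- runif(1, 0.5, 500)
    cc <- complex_from_kd(a, b, kd)
    expect_lt(abs(apparent_kd(cc, a, b) - kd) / kd, 1e-9)
    # and against the independent root-finder
    expect_lt(abs(cc - complex_conc_oracle(a, b, kd)), 1e-8)
  }
})
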