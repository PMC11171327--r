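test_that("noise-free 4PL round-trip recovers parameters within 0.1%", {
  truth <- list(top = 1, bottom = 0, hill = 1, ic50 = 100)
  d <- simulate_dose_response(top = truth$top, bottom = truth$bottom,
                              hill = truth$hill, ic50 = truth$ic50,
                              concentrations = 10^seq(-1, 3.5, length.out = 8),
                              cv = 0)
  fit <- fit_4pl(d$concentration, d$signal)
  expect_true(fit$converged)
  expect_equal(fit$ic50, truth$ic50, tolerance = 1e-3)
  expect_equal(fit$hill, truth$hill, tolerance = 1e-3)
  expect_equal(fit$top, truth$top, tolerance = 1e-3)
  expect_equal(fit$bottom, truth$bottom, tolerance = 1e-3)
})

test_that("round-trip holds across varied true parameter sets", {
  set.seed(8)
  for (i in 1:10) {
    truth <- list(top = runif(1, 0.8, 2), bottom = runif(1, 0, 0.3),
                  hill = runif(1, 0.6, 3), ic50 = 10^runif(1, 0.5, 2.5))
    d <- simulate_dose_response(top = truth$top, bottom = truth$bottom,
                                hill = truth$hill, ic50 = truth$ic50,
                                concentrations = 10^seq(-1, 4, length.out = 10),
                                cv = 0)
    fit <- fit_4pl(d$concentration, d$signal)
    expect_equal(fit$ic50, truth$ic50, tolerance = 1e-3)
    expect_equal(fit$hill, truth$hill, tolerance = 1e-2)
  }
})

test_that("flat data is flagged non-converged, not an error", {
  fit <- fit_4pl(c(1, 10, 100, 1000), rep(0.8, 4))
  expect_false(fit$converged)
  expect_true(is.na(fit$ic50))
})

test_that("the fitted curve passes through its own midpoint at the IC50", {
  d <- simulate_dose_response(top = 1.5, bottom = 0.2, hill = 1.8, ic50 = 40,
                              cv = 0.03, replicates = 3, seed = 5)
  fit <- fit_4pl(d$concentration, d$signal)
  mid <- four_pl(fit$ic50, fit$top, fit$bottom, fit$hill, fit$ic50)
  expect_equal(mid, (fit$top + fit$bottom) / 2, tolerance = 1e-9)
})

test_that("fewer than 4 distinct positive concentrations is an error", {
  expect_error(fit_4pl(c(0, 1, 10, 100), c(1, 0.9, 0.5, 0.1)), "4 distinct")
})

test_that("IC50 is scale-equivariant in concentration and hill invariant", {
  d <- simulate_dose_response(top = 1, bottom = 0, hill = 1.4, ic50 = 80,
                              concentrations = 10^seq(-1, 3.5, length.out = 9),
                              cv = 0)
  f1 <- fit_4pl(d$concentration, d$signal)
  for (c_scale in c(0.01, 1000)) {
    f2 <- fit_4pl(d$concentration * c_scale, d$signal)
    expect_equal(f2$ic50, f1$ic50 * c_scale, tolerance = 1e-6)
    expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  }
})

test_that("potentiation fold is the IC50 ratio and invariant to signal rescale", {
  d1 <- simulate_dose_response(ic50 = 600, concentrations = 10^seq(0, 4, length.out = 8))
  d2 <- simulate_dose_response(ic50 = 100, concentrations = 10^seq(0, 4, length.out = 8))
  f1 <- fit_4pl(d1$concentration, d1$signal)
  f2 <- fit_4pl(d2$concentration, d2$signal)
  pot <- potentiation_fold(f1, f2)
  expect_equal(pot$fold, 6, tolerance = 1e-3)
  expect_equal(potentiation_fold(f1, f1)$fold, 1)
  # common rescaling of both plates' signals leaves the fold unchanged
  f1s <- fit_4pl(d1$concentration, d1$signal * 37)
  f2s <- fit_4pl(d2$concentration, d2$signal * 37)
  expect_equal(potentiation_fold(f1s, f2s)$fold, pot$fold, tolerance = 1e-6)
})

test_that("modulator potentiation reports the ratio with its own label", {
  d1 <- simulate_dose_response(ic50 = 200, concentrations = 10^seq(0, 4, length.out = 8))
  d2 <- simulate_dose_response(ic50 = 100, concentrations = 10^seq(0, 4, length.out = 8))
  f1 <- fit_4pl(d1$concentration, d1$signal)
  f2 <- fit_4pl(d2$concentration, d2$signal)
  pot <- potentiation_with_modulator(f1, f2, label = "O6BG")
  expect_equal(pot$fold, 2, tolerance = 1e-3)
  expect_equal(pot$label, "O6BG")
  expect_equal(potentiation_with_modulator(f1, f1)$fold, 1)
})

test_that("noisy potentiation recovery stays within 15% on the two-plate design", {
  set.seed(17)
  folds <- numeric(50)
  for (i in 1:50) {
    d1 <- simulate_dose_response(ic50 = 600, cv = 0.05, replicates = 3,
                                 concentrations = 10^seq(0, 4, length.out = 8),
                                 seed = 1000 + i)
    d2 <- simulate_dose_response(ic50 = 100, cv = 0.05, replicates = 3,
                                 concentrations = 10^seq(0, 4, length.out = 8),
                                 seed = 5000 + i)
    f1 <- fit_4pl(d1$concentration, d1$signal)
    f2 <- fit_4pl(d2$concentration, d2$signal)
    folds[i] <- potentiation_fold(f1, f2)$fold
  }
  # the recovered fold (averaged over plates) is within 15% of the truth,
  # and individual plates scatter tightly around it
  expect_lt(abs(mean(folds) / 6 - 1), 0.15)
  expect_lt(abs(median(folds) / 6 - 1), 0.15)
  expect_gt(mean(abs(folds / 6 - 1) < 0.15), 0.8)
})
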