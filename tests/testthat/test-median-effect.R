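test_that("noiseless log-linear data are fit exactly", {
  s <- data.frame(dose = c(1, 10, 100), fa = c(1 / 11, 1 / 2, 10 / 11))
  fit <- fit_median_effect(s)
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$Dm, 10, tolerance = 1e-9)
  expect_equal(fit$r_linearity, 1, tolerance = 1e-9)
  expect_equal(fit$n_points_used, 3L)
  # model identity: fa at Dm is 0.5
  expect_equal(fa_at_dose(fit, fit$Dm), 0.5, tolerance = 1e-12)
})

test_that("boundary fa points are excluded and failures are explicit", {
  s <- data.frame(dose = c(1, 10, 100, 1000),
                  fa = c(0, 1 / 2, 10 / 11, 1))
  expect_warning(fit <- fit_median_effect(s), "excluded")
  expect_equal(fit$n_points_used, 2L)
  expect_error(suppressWarnings(
    fit_median_effect(data.frame(dose = c(1, 2), fa = c(0, 1)))),
    "insufficient")
  expect_error(fit_median_effect(data.frame(dose = c(5, 5), fa = c(0.3, 0.6))),
               "degenerate")
})

test_that("dose_for_effect inverts the model", {
  expect_equal(dose_for_effect(list(m = 2, Dm = 4), 0.8), 8)
  fit <- fit_median_effect(
    simulate_dose_response(1.7, 23, c(2, 8, 20, 50, 150)))
  for (x in seq(0.1, 0.9, by = 0.1)) {
    expect_equal(fa_at_dose(fit, dose_for_effect(fit, x)), x,
                 tolerance = 1e-9)
  }
  expect_equal(dose_for_effect(fit, 0.5), fit$Dm, tolerance = 1e-9)
  expect_error(dose_for_effect(fit, 1), "strictly")
})

test_that("noiseless simulate -> fit round trip recovers (m, Dm) exactly", {
  doses <- 10^seq(-1, 2, length.out = 8)
  for (pars in list(c(1, 10), c(2.5, 0.3), c(0.7, 55))) {
    s <- simulate_dose_response(pars[1], pars[2], doses)
    fit <- fit_median_effect(s)
    expect_equal(fit$m, pars[1], tolerance = 1e-9)
    expect_equal(fit$Dm, pars[2], tolerance = 1e-9 * pars[2])
  }
})

test_that("fit is equivariant under dose rescaling", {
  s <- simulate_dose_response(2, 50, 10^seq(0, 3, length.out = 8),
                              noise_sd = 0.05, seed = 4L)
  f1 <- fit_median_effect(s)
  s2 <- transform(s, dose = dose * 7)
  f2 <- fit_median_effect(s2)
  expect_equal(f2$m, f1$m, tolerance = 1e-12)
  expect_equal(f2$Dm, f1$Dm * 7, tolerance = 1e-9)
})

test_that("closed-form and limiting combination indices are exact", {
  fit1 <- list(m = 1, Dm = 10)
  fit2 <- list(m = 1, Dm = 100)
  # closed form
  res <- combination_index(fit1, fit2, 5, 50, 0.8)
  expect_equal(res$Dx1, 40)
  expect_equal(res$Dx2, 400)
  expect_equal(res$ci, 0.25)
  # single-drug limit
  expect_equal(combination_index(fit1, fit2,
                                 dose_for_effect(fit1, 0.6), 0, 0.6)$ci, 1)
  # sham self-combination
  dx <- dose_for_effect(fit1, 0.7)
  expect_equal(combination_index(fit1, fit1, 0.3 * dx, 0.7 * dx, 0.7)$ci, 1)
  expect_error(combination_index(fit1, fit2, 0, 0, 0.5), "not both zero")
})

test_that("CI is invariant under per-drug dose-unit rescaling", {
  fit1 <- list(m = 1.4, Dm = 12)
  fit2 <- list(m = 2.2, Dm = 80)
  combo <- simulate_additive_combination(fit1, fit2,
                                         fa_grid = seq(0.2, 0.8, 0.1),
                                         ratio = 2)
  ci0 <- ci_curve(fit1, fit2, combo)$ci
  scaled1 <- list(m = fit1$m, Dm = fit1$Dm * 2)
  scaled2 <- list(m = fit2$m, Dm = fit2$Dm * 2)
  combo2 <- transform(combo, dose1 = dose1 * 2, dose2 = dose2 * 2)
  expect_equal(ci_curve(scaled1, scaled2, combo2)$ci, ci0,
               tolerance = 1e-12)
})

test_that("constructed additive combinations give CI = 1 exactly", {
  fit1 <- list(m = 1, Dm = 10)
  fit2 <- list(m = 3, Dm = 200)
  combo <- simulate_additive_combination(fit1, fit2,
                                         fa_grid = seq(0.1, 0.9, 0.1),
                                         ratio = 0.5)
  cic <- ci_curve(fit1, fit2, combo)
  expect_equal(cic$ci, rep(1, 9), tolerance = 1e-10)
  # ratio -> 0 limit: d2 -> 0 and d1 -> Dx1(fa)
  small <- simulate_additive_combination(fit1, fit2, fa_grid = 0.4,
                                         ratio = 1e-9)
  expect_equal(small$dose1, dose_for_effect(fit1, 0.4), tolerance = 1e-6)
  expect_lt(small$dose2, 1e-6)
})

test_that("the CC50 table propagates a standard error per condition", {
  fits <- list(
    vehicle = fit_median_effect(
      simulate_dose_response(1.5, 16, 10^seq(-1, 2, length.out = 8),
                             noise_sd = 0.05, seed = 8L)),
    combo = fit_median_effect(
      simulate_dose_response(1.5, 8, 10^seq(-1, 2, length.out = 8),
                             noise_sd = 0.05, seed = 9L)))
  tab <- cc50_table(fits)
  expect_equal(tab$condition, c("vehicle", "combo"))
  expect_true(all(tab$se > 0))
  expect_equal(tab$cc50, c(fits$vehicle$Dm, fits$combo$Dm))
})
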