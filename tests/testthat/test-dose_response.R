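test_that("noiseless Hill data are recovered exactly", {
  cc <- c(0, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4)
  for (h in c(0.7, 1, 2)) {
    dt <- make_dose_table(1e-6, h, cc)
    fit <- fit_ic50(dt$concentration_M, dt$response)
    expect_true(fit$fit_converged)
    expect_lt(abs(fit$ic50 - 1e-6) / 1e-6, 1e-6)
    expect_lt(abs(fit$hill_coefficient - h) / h, 1e-6)
    expect_lt(fit$residual_rms, 1e-8)
  }
})

test_that("the fitted curve passes through 0.5 at the IC50 for any h", {
  dt <- make_dose_table(3e-7, 1.6, c(0, 1e-8, 1e-7, 1e-6, 1e-5))
  fit <- fit_ic50(dt$concentration_M, dt$response)
  expect_equal(predict(fit, fit$ic50), 0.5, tolerance = 1e-9)
  expect_equal(predict(fit, 0), 1)  # anchor by construction
  # predicted curve is monotone non-increasing
  pr <- predict(fit, 10^seq(-9, -3, by = 0.25))
  expect_true(all(diff(pr) <= 0))
})

test_that("fit_ic50 is scale-equivariant in concentration", {
  cc <- c(0, 2e-8, 2e-7, 2e-6, 2e-5)
  dt <- make_dose_table(5e-7, 1.2, cc)
  f1 <- fit_ic50(dt$concentration_M, dt$response)
  s <- 137
  f2 <- fit_ic50(s * dt$concentration_M, dt$response)
  expect_equal(f2$ic50 / f1$ic50, s, tolerance = 1e-6)
  expect_equal(f2$hill_coefficient, f1$hill_coefficient, tolerance = 1e-6)
})

test_that("noisy IC50 recovery stays within 15% in the median (seeded)", {
  cc <- c(0, 10^seq(-8, -4, by = 1))
  errs <- c()
  for (ic50 in c(1e-7, 1e-6, 1e-5)) {
    for (seed in 1:20) {
      dt <- make_dose_table(ic50, 1, cc, noise_sd = 0.03, seed = seed)
      fit <- fit_ic50(dt$concentration_M, dt$response)
      if (fit$fit_converged) errs <- c(errs, abs(fit$ic50 - ic50) / ic50)
    }
  }
  expect_gt(length(errs), 50)
  expect_lt(median(errs), 0.15)
})

test_that("degenerate dose series return a failure flag, not an error", {
  cc <- c(0, 1e-8, 1e-7, 1e-6, 1e-5)
  flat <- fit_ic50(cc, rep(1, 5))
  expect_false(flat$fit_converged)
  expect_match(flat$message, "no dose dependence")

  rising <- fit_ic50(cc, c(1, 0.9, 1.0, 1.1, 1.3))
  expect_false(rising$fit_converged)

  few <- fit_ic50(c(0, 1e-7, 1e-6), c(1, 0.8, 0.3))
  expect_false(few$fit_converged)
  expect_match(few$message, "too few")
  expect_error(predict(few), "did not converge")
})

test_that("free-bottom fitting recovers a non-zero floor", {
  cc <- c(0, 10^seq(-8, -4, by = 0.5))
  r <- ifelse(cc == 0, 1, 0.2 + 0.8 / (1 + (cc / 1e-6)))
  fit <- fit_ic50(cc, r, free_bottom = TRUE)
  expect_true(fit$fit_converged)
  expect_equal(fit$bottom, 0.2, tolerance = 1e-4)
  expect_equal(fit$ic50, 1e-6, tolerance = 1e-4 * 1e-6)
})

test_that("inotropic gains are paired differences of summary means", {
  mk_summary <- function(amp, cv, rv) {
    structure(list(n_beats = 10, beat_rate = 1, pacing_frequency = 1,
                   mean = c(amplitude = amp, contraction_velocity = cv,
                            relaxation_velocity = rv),
                   sd = c(amplitude = 0, contraction_velocity = 0,
                          relaxation_velocity = 0)),
              class = "eht_summary")
  }
  base <- mk_summary(10, 100, 80)
  expect_equal(gain_of_force(base, mk_summary(12, 130, 95))$gain_force, 2)
  g0 <- gain_of_force(base, base)
  expect_equal(g0$gain_force, 0)
  expect_equal(g0$gain_contraction_velocity, 0)
  expect_equal(gain_of_force(base, mk_summary(7, 70, 60))$gain_force, -3)
  expect_error(gain_of_force(base, base, "tissue_A", "tissue_B"), "pairing")
})

test_that("normalization is per tissue, before cross-tissue averaging", {
  doses <- data.frame(
    tissue_id = c("A", "A", "B", "B"),
    concentration_M = c(0, 1e-6, 0, 1e-6),
    amplitude_uN = c(10, 2, 100, 80)
  )
  nd <- normalize_dose_series(doses)
  expect_equal(nd$concentrations, c(0, 1e-6))
  expect_equal(nd$normalized_force, c(1, 0.5))  # (0.2 + 0.8) / 2
  # pooling first would give a different (wrong) answer
  pooled <- mean(c(2, 80)) / mean(c(10, 100))
  expect_false(isTRUE(all.equal(pooled, 0.5)))

  simple <- data.frame(tissue_id = "A", concentration_M = c(0, 1e-6),
                       amplitude_uN = c(10, 5))
  expect_equal(normalize_dose_series(simple)$normalized_force, c(1, 0.5))

  bad <- data.frame(tissue_id = "A", concentration_M = c(0, 1e-6),
                    amplitude_uN = c(0, 5))
  expect_error(normalize_dose_series(bad), "baseline")
  nobase <- data.frame(tissue_id = "A", concentration_M = 1e-6, amplitude_uN = 5)
  expect_error(normalize_dose_series(nobase), "no 0-concentration")
})
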