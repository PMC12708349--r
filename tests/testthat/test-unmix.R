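test_that("a single pure reference is recovered with unit coefficient", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  a <- mixture_spectrum(lib, c(b_H = 0, b_L = 1, c1 = 0, c = 0,
                               slope = 0, intercept = 0))
  fit <- fit_spectrum(a, m)
  co <- fit$coefficients
  expect_equal(unname(co["b_L"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(co[c("b_H", "c1", "c")])), 1e-10)
  expect_lt(abs(co["slope"]) * 560 + abs(co["intercept"]), 1e-7)
  expect_lt(fit$ssr, 1e-16)
})

test_that("noise-free mixtures are recovered to 1e-8 relative", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  truth <- c(b_H = 0.021, b_L = 0.029, c1 = 0.03, c = 0.04,
             slope = 2e-4, intercept = 0.05)
  fit <- fit_spectrum(mixture_spectrum(lib, truth), m)
  expect_equal(unname(fit$coefficients[names(truth)]), unname(truth),
               tolerance = 1e-8)
})

test_that("QR solution equals the normal-equations closed form and the NLS route", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  set.seed(42)
  for (i in 1:5) {
    truth <- c(b_H = runif(1, 0.01, 0.1), b_L = runif(1, 0.01, 0.1),
               c1 = runif(1, 0.01, 0.1), c = runif(1, 0.01, 0.1),
               slope = runif(1, -5e-4, 5e-4), intercept = runif(1, -0.1, 0.2))
    a <- mixture_spectrum(lib, truth)
    # perturb so the fit is nontrivial
    idx <- which(a$wavelengths_nm >= 540 & a$wavelengths_nm <= 580)
    a$values[idx] <- a$values[idx] + 1e-3 * sin(a$wavelengths_nm[idx])
    fit <- fit_spectrum(a, m)
    oracle <- normal_equations_fit(a, m)
    expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-8)
  }
  # independent iterative NLS route (the instrument-software style engine)
  truth <- c(b_H = 0.021, b_L = 0.029, c1 = 0.03, c = 0.04,
             slope = 2e-4, intercept = 0.05)
  a <- mixture_spectrum(lib, truth)
  set.seed(1)
  idx <- which(a$wavelengths_nm >= 540 & a$wavelengths_nm <= 580)
  a$values[idx] <- a$values[idx] + rnorm(length(idx), sd = 1e-3)
  fit <- fit_spectrum(a, m)
  df <- data.frame(y = a$values[idx],
                   bh = lib$refs[idx, "b_H"], bl = lib$refs[idx, "b_L"],
                   c1 = lib$refs[idx, "c1"], cc = lib$refs[idx, "c"],
                   lam = a$wavelengths_nm[idx])
  nls_fit <- minpack.lm::nlsLM(
    y ~ A * bh + B * bl + C * c1 + D * cc + E * lam + F0, data = df,
    start = list(A = 0, B = 0, C = 0, D = 0, E = 0, F0 = 0))
  expect_equal(unname(fit$coefficients),
               unname(coef(nls_fit)[c("A", "B", "C", "D", "E", "F0")]),
               tolerance = 1e-7)
})

test_that("coefficient noise scales with sigma per the linear-model covariance", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  truth <- c(b_H = 0.021, b_L = 0.029, c1 = 0.03, c = 0.04,
             slope = 0, intercept = 0.05)
  a0 <- mixture_spectrum(lib, truth)
  idx <- which(a0$wavelengths_nm >= 540 & a0$wavelengths_nm <= 580)
  X <- cbind(lib$refs[idx, ], slope = lib$grid[idx], intercept = 1)
  sigma <- 1e-4
  sd_analytic <- sqrt(diag(solve(crossprod(X)))) * sigma
  set.seed(99)
  errs <- vapply(1:200, function(s) {
    a <- a0
    a$values[idx] <- a$values[idx] + rnorm(length(idx), sd = sigma)
    fit_spectrum(a, m)$coefficients[1:4] - truth[1:4]
  }, numeric(4))
  med_abs <- apply(abs(errs), 1, median)
  # median |N(0, sd)| = 0.6745 sd; Monte-Carlo slack
  expect_true(all(med_abs > 0.6745 * sd_analytic[1:4] * 0.6))
  expect_true(all(med_abs < 0.6745 * sd_analytic[1:4] * 1.5))
})

test_that("duplicated references are refused with a conditioning error", {
  lib <- quartet_library()
  refs <- lib$refs
  refs[, "c1"] <- refs[, "c"]
  lib2 <- reference_library(lib$grid, refs, band_nm = lib$band_nm)
  m <- unmix_model(lib2)
  a <- mixture_spectrum(lib2, c(b_H = 0.02, b_L = 0.03, c1 = 0.03, c = 0.04,
                                slope = 0, intercept = 0))
  expect_error(fit_spectrum(a, m), "condition number|rank")
})

test_that("fb_L is the b_L fraction of total b-heme amplitude", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  # symmetric case -> 0.5
  a <- mixture_spectrum(lib, c(b_H = 0.04, b_L = 0.04, c1 = 0.02, c = 0.02,
                               slope = 0, intercept = 0))
  expect_equal(compute_fbl(fit_spectrum(a, m))$value, 0.5, tolerance = 1e-9)
  # 0.2 / (0.2 + 0.8)
  a <- mixture_spectrum(lib, c(b_H = 0.8, b_L = 0.2, c1 = 0, c = 0,
                               slope = 0, intercept = 0))
  expect_equal(compute_fbl(fit_spectrum(a, m))$value, 0.2, tolerance = 1e-9)
  # forward-model oracle: fbl* = 0.62 at total 0.05 OD
  co <- default_coefs(fbl = 0.62, b_total = 0.05)
  fit <- fit_spectrum(mixture_spectrum(lib, unlist(co)), m)
  fbl <- compute_fbl(fit)
  expect_equal(fbl$value, 0.62, tolerance = 1e-8)
  expect_false(fbl$negative_amplitude)
})

test_that("fb_L errors when undefined and flags negative amplitudes", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  a <- mixture_spectrum(lib, c(b_H = 0, b_L = 0, c1 = 0.05, c = 0.05,
                               slope = 0, intercept = 0))
  fit <- fit_spectrum(a, m)
  fit$coefficients[c("b_H", "b_L")] <- 0  # exact zeros
  expect_error(compute_fbl(fit), "zero")
  a <- mixture_spectrum(lib, c(b_H = 0.05, b_L = -0.01, c1 = 0.02, c = 0.02,
                               slope = 0, intercept = 0))
  expect_true(compute_fbl(fit_spectrum(a, m))$negative_amplitude)
})

test_that("SNR statistic follows the quartet-sum / ssr convention", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  co <- default_coefs()
  fit <- fit_spectrum(mixture_spectrum(lib, unlist(co)), m)
  # exactly zero residuals -> infinite snr, never excluded
  perfect <- fit
  perfect$ssr <- 0
  perfect <- compute_snr_and_flag(perfect, m)
  expect_identical(perfect$snr, Inf)
  expect_false(perfect$excluded)
  # a noise-free forward-model fit is far above the threshold
  fit <- compute_snr_and_flag(fit, m)
  expect_gt(fit$snr, 1e6)
  expect_false(fit$excluded)
  # threshold arithmetic: numerator 1.0, ssr 0.02 -> snr 50 -> excluded
  fake <- fit
  fake$component_spectra <- fake$component_spectra /
    sum(fake$component_spectra[, c("b_H", "b_L", "c1", "c")])
  fake$ssr <- 0.02
  fake <- compute_snr_and_flag(fake, m)
  expect_equal(fake$snr, 50)
  expect_true(fake$excluded)
})

test_that("SNR decreases strictly along a noise ladder with matched draws", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  a0 <- mixture_spectrum(lib, unlist(default_coefs()))
  idx <- which(a0$wavelengths_nm >= 540 & a0$wavelengths_nm <= 580)
  set.seed(5)
  z <- rnorm(length(idx))
  sigmas <- c(1e-5, 1e-4, 1e-3, 1e-2)
  snrs <- vapply(sigmas, function(s) {
    a <- a0
    a$values[idx] <- a$values[idx] + s * z
    compute_snr_and_flag(fit_spectrum(a, m), m)$snr
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
  # exclusion decisions match direct evaluation of the formula
  excl <- vapply(sigmas, function(s) {
    a <- a0
    a$values[idx] <- a$values[idx] + s * z
    fit <- compute_snr_and_flag(fit_spectrum(a, m), m)
    direct <- sum(fit$component_spectra[, c("b_H", "b_L", "c1", "c")]) /
      sum(fit$residuals^2)
    expect_equal(fit$snr, max(0, direct))
    fit$excluded
  }, logical(1))
  expect_identical(excl, snrs < 100)
})

test_that("path-length scaling moves coefficients but not fb_L", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  a1 <- mixture_spectrum(lib, unlist(default_coefs()))
  fit1 <- fit_spectrum(a1, m)
  f1 <- compute_fbl(fit1)$value
  for (k in c(0.5, 2, 10)) {
    ak <- spectrum(a1$wavelengths_nm, a1$values * k, role = "absorbance")
    fitk <- fit_spectrum(ak, m)
    expect_equal(unname(fitk$coefficients[1:4]),
                 unname(fit1$coefficients[1:4] * k), tolerance = 1e-8)
    expect_lt(abs(compute_fbl(fitk)$value - f1), 1e-10)
  }
})

test_that("an added line changes only the baseline coefficients", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  a1 <- mixture_spectrum(lib, unlist(default_coefs()))
  fit1 <- fit_spectrum(a1, m)
  g <- 3e-4; h <- -0.12
  a2 <- spectrum(a1$wavelengths_nm, a1$values + g * a1$wavelengths_nm + h,
                 role = "absorbance")
  fit2 <- fit_spectrum(a2, m)
  expect_equal(unname(fit2$coefficients[1:4]), unname(fit1$coefficients[1:4]),
               tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients["slope"]),
               unname(fit1$coefficients["slope"]) + g, tolerance = 1e-8)
})

test_that("residuals are orthogonal to every design column", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  a <- mixture_spectrum(lib, unlist(default_coefs()))
  idx <- which(a$wavelengths_nm >= 540 & a$wavelengths_nm <= 580)
  set.seed(8)
  a$values[idx] <- a$values[idx] + rnorm(length(idx), sd = 5e-3)
  fit <- fit_spectrum(a, m)
  X <- cbind(lib$refs[idx, ], lib$grid[idx], 1)
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
  # reconstruction identities
  expect_equal(fit$fitted + fit$residuals, fit$data)
  base <- fit$coefficients["slope"] * fit$lambda + fit$coefficients["intercept"]
  expect_equal(rowSums(fit$component_spectra) + unname(base), fit$fitted,
               tolerance = 1e-12)
})

test_that("nonnegative mode clamps negative chromophores and keeps others close", {
  lib <- quartet_library()
  mn <- unmix_model(lib, nonneg = TRUE)
  # construct data whose unconstrained fit drives b_L negative
  a <- mixture_spectrum(lib, c(b_H = 0.06, b_L = -0.02, c1 = 0.03, c = 0.04,
                               slope = 0, intercept = 0.02))
  fit <- fit_spectrum(a, mn)
  expect_true(all(fit$coefficients[c("b_H", "b_L", "c1", "c")] >= 0))
})

test_that("fit_series tracks a step change and flags injected noisy spectra", {
  lib <- quartet_library()
  m <- unmix_model(lib)
  # constant series -> constant coefficients
  co <- default_coefs()[rep(1, 8), ]
  sim <- simulate_spectrum_series(co, lib)
  res <- fit_series(sim$record, m, window = 4)
  expect_equal(nrow(res), 5)
  expect_lt(diff(range(res$fbl)), 1e-10)
  # step in true fb_L: reaches the new level within window - 1 samples
  co2 <- rbind(default_coefs(fbl = 0.3)[rep(1, 10), ],
               default_coefs(fbl = 0.6)[rep(1, 10), ])
  sim2 <- simulate_spectrum_series(co2, lib)
  res2 <- fit_series(sim2$record, m, window = 4)
  # last pre-step window ends at t=10; full new level from t >= 14
  expect_equal(res2$fbl[res2$time_s >= 14], rep(0.6, 7), tolerance = 1e-8)
  expect_equal(res2$fbl[res2$time_s <= 10], rep(0.3, 7), tolerance = 1e-8)
  # inject 5 very noisy spectra into a 60-spectrum series
  co3 <- heart_coefs()[rep(1, 60), ]
  sim3 <- simulate_spectrum_series(co3, lib, noise_sd_counts = 20, seed = 12)
  noisy_idx <- 30:34
  set.seed(13)
  tr <- sim3$record$transmissions
  tr[, noisy_idx] <- tr[, noisy_idx] + rnorm(length(tr[, noisy_idx]), sd = 2e4)
  tr[tr <= max(sim3$record$dark)] <- max(sim3$record$dark) + 1
  rec3 <- raw_optical_record(sim3$record$wavelengths_nm, sim3$record$incident,
                             sim3$record$dark, tr, times_s = sim3$record$times_s)
  res3 <- fit_series(rec3, m, window = 4)
  # windows touching a noisy spectrum must be exactly those breaching the rule
  direct <- vapply(seq_len(nrow(res3)), function(i) {
    fitrow <- res3[i, ]
    fitrow$snr < 100
  }, logical(1))
  expect_identical(res3$excluded, direct)
  touching <- res3$time_s %in% (min(noisy_idx)):(max(noisy_idx) + 3)
  expect_true(all(res3$excluded[touching]))
  expect_false(any(res3$excluded[!touching]))
})

test_that("fit band defaults widen when myoglobin is in the library", {
  lib_mb <- make_reference_library(default_band_models(include_mb = TRUE),
                                   band_nm = c(535, 585))
  m <- unmix_model(lib_mb)
  expect_equal(m$band_nm, c(535, 585))
  m2 <- unmix_model(quartet_library())
  expect_equal(m2$band_nm, c(540, 580))
})
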