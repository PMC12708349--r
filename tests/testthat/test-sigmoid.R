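true_params <- c(bottom = 0.15, top = 0.65, v50_mV = 140, hill = 0.03)

test_that("noise-free calibration points recover the 4PL to 1e-6 relative", {
  pts <- simulate_calibration_points(sigma_fbl = 0)
  cv <- fit_calibration(pts)
  expect_equal(unname(cv$parameters), unname(true_params),
               tolerance = 1e-6)
  expect_equal(cv$domain_mV, c(60, 208))
})

test_that("fit matches an independent optim-based least-squares oracle", {
  pts <- simulate_calibration_points(sigma_fbl = 0.02, seed = 21)
  cv <- fit_calibration(pts)
  obj <- function(p) sum((pts$fbl - (p[1] + (p[2] - p[1]) /
                                       (1 + 10^((p[3] - pts$delta_psi_mV) * p[4]))))^2)
  oracle <- optim(c(0.15, 0.65, 140, 0.03), obj, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-15))
  oracle <- optim(oracle$par, obj, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-15))
  expect_lte(cv$fit_info$ssr, oracle$value + 1e-10)
  expect_equal(unname(cv$parameters), oracle$par, tolerance = 1e-3)
})

test_that("degenerate and non-spanning inputs are refused", {
  flat <- data.frame(delta_psi_mV = seq(60, 200, length.out = 10),
                     fbl = rep(0.4, 10))
  expect_error(fit_calibration(flat), "degenerate")
  expect_error(fit_calibration(flat[1:4, ]), "at least 6")
  onesided <- data.frame(delta_psi_mV = rep(100, 8),
                         fbl = seq(0.2, 0.6, length.out = 8))
  expect_error(fit_calibration(onesided), "span")
})

test_that("curve evaluation has midpoint symmetry, asymptotes and monotonicity", {
  cv <- default_true_curve()
  p <- cv$parameters
  expect_equal(as.numeric(evaluate_curve(cv, p["v50_mV"])),
               unname((p["bottom"] + p["top"]) / 2))
  expect_equal(as.numeric(evaluate_curve(cv, -1e6)), unname(p["bottom"]),
               tolerance = 1e-12)
  expect_equal(as.numeric(evaluate_curve(cv, 1e6)), unname(p["top"]),
               tolerance = 1e-12)
  grid <- seq(-50, 350, by = 1)
  expect_true(all(diff(as.numeric(evaluate_curve(cv, grid))) > 0))
  # closed-form oracle: independent re-implementation of the logistic
  direct <- p["bottom"] + (p["top"] - p["bottom"]) /
    (1 + 10^((p["v50_mV"] - grid) * p["hill"]))
  expect_equal(as.numeric(evaluate_curve(cv, grid)), unname(direct),
               tolerance = 1e-14)
})

test_that("inverse prediction round-trips exactly on the interior", {
  cv <- default_true_curve()
  p <- cv$parameters
  # midpoint -> v50, uncensored
  inv <- invert_curve(cv, unname((p["bottom"] + p["top"]) / 2))
  expect_equal(inv$delta_psi_mV, unname(p["v50_mV"]), tolerance = 1e-9)
  expect_identical(inv$censored, "none")
  # 50-point round trip over the interior (inside the 1% asymptote guards)
  half_width <- log10(1 / 0.012 - 1) / unname(p["hill"])
  psis <- seq(max(cv$domain_mV[1], unname(p["v50_mV"]) - half_width),
              min(cv$domain_mV[2], unname(p["v50_mV"]) + half_width),
              length.out = 50)
  rt <- invert_curve(cv, as.numeric(evaluate_curve(cv, psis)))
  expect_true(all(rt$censored == "none"))
  expect_lt(max(abs(rt$delta_psi_mV - psis)), 1e-9)
  expect_error(invert_curve(cv, 1.2), "\\[0, 1\\]")
})

test_that("values beyond the asymptote guard are censored at the domain bounds", {
  cv <- default_true_curve()
  p <- cv$parameters
  span <- unname(p["top"] - p["bottom"])
  hi <- invert_curve(cv, unname(p["top"]) - 0.005 * span)
  expect_identical(hi$censored, "above")
  expect_equal(hi$delta_psi_mV, cv$domain_mV[2])
  lo <- invert_curve(cv, unname(p["bottom"]) + 0.005 * span)
  expect_identical(lo$censored, "below")
  expect_equal(lo$delta_psi_mV, cv$domain_mV[1])
  # interior fb_L mapping above the calibrated domain is censored too
  above_dom <- as.numeric(evaluate_curve(cv, cv$domain_mV[2] + 30))
  out <- invert_curve(cv, above_dom)
  expect_identical(out$censored, "above")
  expect_equal(out$delta_psi_mV, cv$domain_mV[2])
})

test_that("v50 recovery from noisy condition means is nearly unbiased", {
  v50s <- vapply(1:150, function(s) {
    pts <- simulate_calibration_points(sigma_fbl = 0.02, seed = 400 + s)
    fit_calibration(pts)$parameters[["v50_mV"]]
  }, numeric(1))
  expect_lt(abs(mean(v50s) - 140), 1)
})

test_that("fit is invariant to point order and consistent under mV -> V rescaling", {
  pts <- simulate_calibration_points(sigma_fbl = 0.02, seed = 31)
  cv <- fit_calibration(pts)
  shuffled <- pts[sample(nrow(pts)), ]
  cv2 <- fit_calibration(shuffled)
  expect_equal(cv$parameters, cv2$parameters, tolerance = 1e-8)
  # volts instead of millivolts: v50 and hill rescale, asymptotes unchanged
  ptsV <- pts
  ptsV$delta_psi_mV <- ptsV$delta_psi_mV / 1000
  cvV <- fit_calibration(ptsV, hill_starts = c(10, 30, 100))
  expect_equal(cvV$parameters[["bottom"]], cv$parameters[["bottom"]],
               tolerance = 1e-5)
  expect_equal(cvV$parameters[["top"]], cv$parameters[["top"]],
               tolerance = 1e-5)
  expect_equal(cvV$parameters[["v50_mV"]] * 1000, cv$parameters[["v50_mV"]],
               tolerance = 1e-4)
  expect_equal(cvV$parameters[["hill"]] / 1000, cv$parameters[["hill"]],
               tolerance = 1e-4)
})

test_that("bootstrap bands degenerate without noise, nest across levels", {
  pts0 <- simulate_calibration_points(sigma_fbl = 0)
  cv0 <- fit_calibration(pts0)
  grid <- seq(80, 190, by = 10)
  band0 <- confidence_band(cv0, pts0, grid, B = 200, seed = 1)
  expect_lt(max(band0$upper - band0$lower), 1e-6)
  pts <- simulate_calibration_points(sigma_fbl = 0.02, seed = 51)
  cv <- fit_calibration(pts)
  b95 <- confidence_band(cv, pts, grid, level = 0.95, B = 300, seed = 2)
  b80 <- confidence_band(cv, pts, grid, level = 0.80, B = 300, seed = 2)
  expect_true(all(b95$upper - b95$lower >= b80$upper - b80$lower - 1e-12))
  # reproducible under a fixed seed
  b95b <- confidence_band(cv, pts, grid, level = 0.95, B = 300, seed = 2)
  expect_identical(b95, b95b)
})
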