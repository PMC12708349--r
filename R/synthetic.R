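#' Wavelength-grid presets
#'
#' `heart_grid()` mimics the transmural heart spectrometer (1,024 points,
#' 400-800 nm); `mito_grid()` the mitochondrial-suspension instrument
#' (1,044 points, 348-745 nm).
#'
#' @return numeric wavelength grid (nm).
#' @export
heart_grid <- function() seq(400, 800, length.out = 1024)

#' @rdname heart_grid
#' @export
mito_grid <- function() seq(348, 745, length.out = 1044)

#' Default Gaussian band models for the alpha-band chromophores
#'
#' Each chromophore is one or two Gaussian sub-bands standing in for the
#' empirically collected references: cytochrome c at 550 nm, c1 at 552 nm,
#' heme b_H at 562 nm, and heme b_L with its main feature at 566 nm plus
#' the 558 nm shoulder (height 0.5) that characterizes the b_L difference
#' spectrum. With myoglobin included, MbO has twin bands near 542/580 nm
#' and MbD one broad band near 556 nm.
#'
#' @param include_mb include MbO/MbD models (default FALSE).
#' @return named list; each element a `data.frame(center_nm, sigma_nm,
#'   height)` of sub-bands.
#' @export
default_band_models <- function(include_mb = FALSE) {
  bm <- list(
    b_H = data.frame(center_nm = 562, sigma_nm = 3.5, height = 1),
    b_L = data.frame(center_nm = c(566, 558), sigma_nm = c(3.8, 3.5),
                     height = c(1, 0.5)),
    c1  = data.frame(center_nm = 552, sigma_nm = 4.2, height = 1),
    c   = data.frame(center_nm = 550, sigma_nm = 4.2, height = 1))
  if (include_mb) {
    bm$MbO <- data.frame(center_nm = c(542, 580), sigma_nm = c(8, 7),
                         height = c(1, 0.9))
    bm$MbD <- data.frame(center_nm = 556, sigma_nm = 12, height = 1)
  }
  bm
}

#' Generate a synthetic reference library from band models
#'
#' Sums the Gaussian sub-bands of each model on the grid and unit-peak
#' normalizes within the fit band. The condition number of the implied
#' unmixing design (references plus line) over the band is computed and
#' attached; coincident band models trigger a collinearity warning.
#'
#' @param band_models named list of band models (see
#'   [default_band_models()]); must include the quartet b_H, b_L, c1, c.
#' @param grid wavelength grid, default [heart_grid()].
#' @param band_nm normalization/fit band, default `c(540, 580)` (use
#'   `c(535, 585)` with myoglobin).
#' @return a [reference_library()] with attribute `condition_number`.
#' @export
make_reference_library <- function(band_models = default_band_models(),
                                   grid = heart_grid(),
                                   band_nm = c(540, 580)) {
  if (min(grid) > min(band_nm) || max(grid) < max(band_nm))
    stop("grid must cover the fit band", call. = FALSE)
  refs <- vapply(band_models, function(bm) {
    rowSums(vapply(seq_len(nrow(bm)), function(i)
      bm$height[i] * exp(-0.5 * ((grid - bm$center_nm[i]) / bm$sigma_nm[i])^2),
      numeric(length(grid))))
  }, numeric(length(grid)))
  lib <- reference_library(grid, refs, band_nm = band_nm)
  idx <- band_index(grid, band_nm)
  X <- cbind(lib$refs[idx, , drop = FALSE], grid[idx], 1)
  kap <- kappa(X, exact = TRUE)
  centers <- vapply(band_models, function(bm)
    bm$center_nm[which.max(bm$height)], numeric(1))
  if (anyDuplicated(centers) || !is.finite(kap) || kap > 1e8)
    warning(sprintf("near-collinear reference set (condition number %.3g)",
                    kap), call. = FALSE)
  attr(lib, "condition_number") <- kap
  lib
}

# smooth broadband incident-light profile (counts) and flat dark current
default_incident <- function(grid) {
  5e4 * exp(-0.5 * ((grid - 580) / 120)^2) + 1e4
}
default_dark <- function(grid) rep(1000, length(grid))

#' Simulate a timestamped spectral record from coefficient trajectories
#'
#' Forward model of the unmixing equation: at each timepoint the absorbance
#' is the coefficient-weighted sum of the library references plus the line
#' `slope * lambda + intercept`; absorbance is inverted to transmitted
#' counts against a stored incident/dark pair, and Gaussian noise is added
#' in the count domain (matching the instrument, and inducing the
#' heteroscedasticity the SNR rule must handle). Seed-deterministic, with a
#' truth table aligned row-for-row.
#'
#' @param coefs `data.frame`/matrix of true coefficient trajectories: one
#'   named column per library chromophore plus `slope` and `intercept`; one
#'   row per timepoint.
#' @param library a [reference_library()].
#' @param noise_sd_counts Gaussian count-noise SD, default 0.
#' @param seed RNG seed (used when noise > 0).
#' @param incident,dark instrument profiles; defaults supplied.
#' @param times_s timestamps, default 1, 2, ... seconds.
#' @return list: `record` ([raw_optical_record()]), `truth` (`data.frame`
#'   with `time_s`, coefficients, and true `fbl`).
#' @export
simulate_spectrum_series <- function(coefs, library, noise_sd_counts = 0,
                                     seed = NULL, incident = NULL,
                                     dark = NULL, times_s = NULL) {
  stopifnot(inherits(library, "mitopsi_library"))
  coefs <- as.data.frame(coefs)
  chrom <- colnames(library$refs)
  if (!all(c(chrom, "slope", "intercept") %in% names(coefs)))
    stop("coefs needs one column per library chromophore plus slope and intercept",
         call. = FALSE)
  if (noise_sd_counts < 0) stop("noise sd must be >= 0", call. = FALSE)
  grid <- library$grid
  n_t <- nrow(coefs)
  if (is.null(incident)) incident <- default_incident(grid)
  if (is.null(dark)) dark <- default_dark(grid)
  if (is.null(times_s)) times_s <- seq_len(n_t)
  A <- library$refs %*% t(as.matrix(coefs[, chrom, drop = FALSE])) +
    outer(grid, coefs$slope) +
    matrix(coefs$intercept, length(grid), n_t, byrow = TRUE)
  tr <- (incident - dark) * 10^(-A) + dark
  if (any(tr <= dark * 0))
    stop("coefficients produce nonpositive transmitted counts", call. = FALSE)
  if (noise_sd_counts > 0) {
    if (!is.null(seed)) set.seed(seed)
    tr <- tr + matrix(stats::rnorm(length(tr), sd = noise_sd_counts),
                      nrow(tr), ncol(tr))
    if (any(tr - dark <= 0))
      stop("count noise drove transmitted counts below dark current",
           call. = FALSE)
  }
  truth <- cbind(data.frame(time_s = times_s), coefs)
  truth$fbl <- coefs$b_L / (coefs$b_L + coefs$b_H)
  list(record = raw_optical_record(grid, incident, dark, tr,
                                   times_s = times_s),
       truth = truth)
}

#' Count-noise level giving a target signal-to-noise statistic
#'
#' Analytically inverts the SNR statistic: for a given true coefficient row,
#' the expected sum of squared residuals of the band fit is
#' `(1 - p/n) * sum(sigma_A^2) / window`, with per-wavelength absorbance
#' noise `sigma_A = sigma_counts / (ln 10 * (T - D))`. Solving
#' `numerator / ssr = target` for `sigma_counts` gives the count-noise SD
#' at which a fit of a `window`-average of spectra attains the requested
#' statistic in expectation.
#'
#' @param coef_row single-row coefficient data.frame (as for
#'   [simulate_spectrum_series()]).
#' @param library a [reference_library()].
#' @param band_nm fit band, default `c(540, 580)`.
#' @param window rolling-average window the fit will use, default 1.
#' @param target_snr desired SNR statistic.
#' @param incident,dark instrument profiles; defaults supplied.
#' @return count-noise SD (counts).
#' @export
noise_for_target_snr <- function(coef_row, library, band_nm = c(540, 580),
                                 window = 1, target_snr = 1000,
                                 incident = NULL, dark = NULL) {
  grid <- library$grid
  if (is.null(incident)) incident <- default_incident(grid)
  if (is.null(dark)) dark <- default_dark(grid)
  idx <- band_index(grid, band_nm)
  chrom <- colnames(library$refs)
  a <- drop(library$refs[idx, , drop = FALSE] %*%
              as.numeric(coef_row[1, chrom])) +
    grid[idx] * coef_row$slope[1] + coef_row$intercept[1]
  tr <- (incident[idx] - dark[idx]) * 10^(-a) + dark[idx]
  quartet <- intersect(c("b_H", "b_L", "c1", "c"), chrom)
  num <- sum(library$refs[idx, quartet, drop = FALSE] %*%
               as.numeric(coef_row[1, quartet]))
  p <- ncol(library$refs) + 2
  n <- length(idx)
  ssr_target <- num / target_snr
  s2 <- sum((1 / (log(10) * (tr - dark[idx])))^2)
  sqrt(ssr_target * window * n / ((n - p) * s2))
}

#' Default ground-truth calibration curve for simulations
#'
#' 4PL with bottom 0.15, top 0.65, v50 140 mV, hill 0.03 per mV and a
#' calibrated domain of 60-208 mV. Consistent with the observable anchors:
#' fb_L about 0.18-0.20 near 101 mV, about 0.58 at 166 mV, and an fb_L
#' ceiling near 0.645 at the 208 mV domain top.
#'
#' @param domain_mV calibrated potential range, default `c(60, 208)`.
#' @return a `mitopsi_curve`.
#' @export
default_true_curve <- function(domain_mV = c(60, 208)) {
  new_calibration_curve(0.15, 0.65, 140, 0.03, covariance = NULL,
                        domain_mV = domain_mV)
}

#' Simulate a paired optical + electrode titration experiment
#'
#' Emulates the calibration protocol: de-energized mitochondria receive six
#' equal probe additions up to the total concentration while the electrode
#' reports Nernstian plateaus; the suspension is then stepped through a
#' piecewise-constant membrane-potential schedule. For each level the
#' external probe concentration follows from probe mass balance and the
#' Nernst relation (with the binding correction), the electrode voltage
#' from the Nernstian electrode law, and the optical stream from the true
#' calibration curve: fb_L* = curve(psi*), split into b-heme coefficients
#' at the configured total b amplitude. Both instrument streams are emitted
#' with an aligned truth table.
#'
#' @param schedule `data.frame(psi_mV, duration_s)` with >= 2 levels of the
#'   post-energization membrane-potential program.
#' @param curve true calibration curve, default [default_true_curve()].
#' @param library reference library, default quartet on [heart_grid()].
#' @param electrode list: `slope_mV_per_decade` (default 59),
#'   `intercept_mV` (default -10), `settle_tau_s` (default 1.5).
#' @param total_b_amp total b-heme amplitude (OD), default 0.05
#'   (mitochondrial-suspension scale); `c1_amp` 0.03, `c_amp` 0.04.
#' @param c1_amp,c_amp cytochrome amplitudes (OD).
#' @param protein_mg protein in bath (mg), default 6.
#' @param bath_volume_ml bath volume, default 5.5 ml.
#' @param total_probe_uM final probe concentration, default 2.17.
#' @param n_additions calibration additions, default 6.
#' @param addition_spacing_s spacing of calibration additions (s), default 60.
#' @param binding_mg_per_uL binding correction, default 0.17.
#' @param noise list: `counts` (optical count SD, default 0), `mV`
#'   (electrode voltage SD, default 0).
#' @param seed RNG seed.
#' @return list: `record`, `trace` (an [electrode_trace()]), `truth`
#'   (per-second psi, fbl, c_out, c_in, coefficients), `level_windows`
#'   (plateau windows of the schedule levels), `curve`.
#' @export
simulate_titration_experiment <- function(
    schedule, curve = default_true_curve(),
    library = make_reference_library(),
    electrode = list(slope_mV_per_decade = 59, intercept_mV = -10,
                     settle_tau_s = 1.5),
    total_b_amp = 0.05, c1_amp = 0.03, c_amp = 0.04,
    protein_mg = 6, bath_volume_ml = 5.5, total_probe_uM = 2.17,
    n_additions = 6, addition_spacing_s = 60, binding_mg_per_uL = 0.17,
    noise = list(counts = 0, mV = 0), seed = NULL) {
  schedule <- as.data.frame(schedule)
  if (nrow(schedule) < 2)
    stop("schedule needs at least 2 membrane-potential levels", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  q <- bath_volume_ml * binding_mg_per_uL / protein_mg
  c_out_for_psi <- function(psi) {
    r <- 10^(psi / 61.5)
    total_probe_uM * q / (1e-3 * r + q)
  }
  # timeline: calibration additions, then schedule levels
  add_times <- addition_spacing_s * (seq_len(n_additions) - 1) + 10
  cal_end <- add_times[n_additions] + addition_spacing_s
  lvl_starts <- cal_end + c(0, cumsum(schedule$duration_s))[seq_len(nrow(schedule))]
  t_end <- cal_end + sum(schedule$duration_s)
  times <- seq_len(t_end)
  # external probe concentration over time (uM)
  per_add <- total_probe_uM / n_additions
  c_cal <- per_add * findInterval(times, add_times)  # cumulative during calibration
  c_out <- c_cal
  psi_true <- rep(0, length(times))
  for (i in seq_len(nrow(schedule))) {
    sel <- times >= lvl_starts[i]
    c_out[sel] <- c_out_for_psi(schedule$psi_mV[i])
    psi_true[sel] <- schedule$psi_mV[i]
  }
  # first-order electrode settling toward the instantaneous target
  tau <- electrode$settle_tau_s %||% 0
  c_obs <- c_out
  if (tau > 0) {
    for (i in seq_along(times)[-1])
      c_obs[i] <- c_obs[i - 1] + (c_out[i] - c_obs[i - 1]) *
        (1 - exp(-1 / tau))
  }
  c_obs[c_obs <= 0] <- NA
  volt <- electrode$intercept_mV +
    electrode$slope_mV_per_decade * log10(c_obs)
  volt[is.na(volt)] <- electrode$intercept_mV +
    electrode$slope_mV_per_decade * log10(per_add / 10)
  if (noise$mV > 0) volt <- volt + stats::rnorm(length(volt), sd = noise$mV)
  trace <- electrode_trace(times, volt,
                           additions = data.frame(time_s = add_times,
                                                  amount_nmol = per_add *
                                                    bath_volume_ml),
                           bath_volume_ml = bath_volume_ml,
                           protein_mg = protein_mg,
                           total_probe_uM = total_probe_uM)
  # optical stream: fbl* from the true curve (flag levels outside its domain)
  fbl_true <- as.numeric(evaluate_curve(curve, psi_true))
  censored_truth <- psi_true > curve$domain_mV[2] | psi_true < curve$domain_mV[1]
  coefs <- data.frame(b_H = (1 - fbl_true) * total_b_amp,
                      b_L = fbl_true * total_b_amp,
                      c1 = c1_amp, c = c_amp, slope = 0, intercept = 0)
  sim <- simulate_spectrum_series(coefs, library,
                                  noise_sd_counts = noise$counts,
                                  times_s = times)
  truth <- data.frame(time_s = times, psi_mV = psi_true, fbl = fbl_true,
                      c_out_uM = c_out,
                      c_in_mM = (total_probe_uM - c_out) * bath_volume_ml /
                        protein_mg * binding_mg_per_uL,
                      censored = censored_truth)
  windows <- data.frame(psi_mV = schedule$psi_mV,
                        t0_s = lvl_starts + 15,
                        t1_s = lvl_starts + schedule$duration_s - 1)
  list(record = sim$record, trace = trace, truth = truth,
       level_windows = windows, curve = curve)
}

#' Simulate a full ischemia-reperfusion optical recording
#'
#' Ground-truth membrane-potential trajectory: control plateau; at the
#' onset of ischemia a fast exponential drop to the ischemic plateau; a
#' secondary linear decline to the minimum beginning at a configurable time
#' into ischemia (glycolytic failure / hypercontracture); on reperfusion a
#' fast exponential rebound to the control level followed by a slow late
#' drift. From the hypercontracture event onward a path-length multiplier
#' scales every chromophore coefficient (true fb_L is unaffected by
#' construction). Cytochrome c reduction rises at the onset of ischemia and
#' reverses on reperfusion. All noise is count-domain.
#'
#' @param timeline an [experiment_timeline()], default 10/20/20 min.
#' @param curve true calibration curve, default [default_true_curve()].
#' @param include_mb include myoglobin (wild-type heart style): adds
#'   MbO/MbD trajectories and the 535-585 nm band library.
#' @param control_psi_mV control potential, default 166.
#' @param plateau_psi_mV ischemic plateau, default 133.
#' @param min_psi_mV minimum during late ischemia, default 92.
#' @param end_psi_mV potential at the end of reperfusion, default 150.
#' @param decline_onset_s secondary-decline onset, seconds after the start
#'   of ischemia, default 780 (13 min).
#' @param decline_duration_s duration of the rapid secondary decline,
#'   default 120.
#' @param drop_tau_s,rebound_tau_s exponential time constants of the
#'   ischemic drop and reperfusion rebound (s), defaults 20 and 15.
#' @param path_step path-length multiplier applied from hypercontracture
#'   (end of the secondary decline), default 1.3.
#' @param amplitudes list of transmural chromophore amplitudes (OD):
#'   `b_total` 0.2, `c1` 0.12, `c` 0.16, `mb` 0.4.
#' @param snr_target per-raw-spectrum SNR statistic the default count noise
#'   is calibrated to, default 2000; overridden by `noise_sd_counts`.
#' @param noise_sd_counts explicit count-noise SD (NULL = derive from
#'   `snr_target`; 0 = noise-free).
#' @param seed RNG seed.
#' @return list: `record`, `truth` (time, psi, fbl, coefficients,
#'   `path_mult`, cytc amplitude), `events` (secondary-decline onset and
#'   hypercontracture times), `timeline`, `curve`, `library`.
#' @export
simulate_ir_experiment <- function(
    timeline = default_ir_timeline(), curve = default_true_curve(),
    include_mb = FALSE, control_psi_mV = 166, plateau_psi_mV = 133,
    min_psi_mV = 92, end_psi_mV = 150, decline_onset_s = 780,
    decline_duration_s = 120, drop_tau_s = 20, rebound_tau_s = 15,
    path_step = 1.3,
    amplitudes = list(b_total = 0.2, c1 = 0.12, c = 0.16, mb = 0.4),
    snr_target = 2000, noise_sd_counts = NULL, seed = NULL) {
  ph <- timeline$phases
  need <- c("control", "ischemia", "reperfusion")
  if (!all(need %in% ph$name))
    stop("timeline must contain control, ischemia and reperfusion phases",
         call. = FALSE)
  t_isc <- ph$start_s[ph$name == "ischemia"]
  t_rep <- ph$start_s[ph$name == "reperfusion"]
  t_end <- ph$end_s[ph$name == "reperfusion"]
  if (t_isc + decline_onset_s + decline_duration_s > t_rep)
    stop("secondary decline does not fit inside the ischemic phase",
         call. = FALSE)
  times <- seq_len(t_end)
  onset <- t_isc + decline_onset_s
  hyper <- onset + decline_duration_s
  psi <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    psi[i] <- if (t < t_isc) control_psi_mV
    else if (t < onset)
      plateau_psi_mV + (control_psi_mV - plateau_psi_mV) *
        exp(-(t - t_isc) / drop_tau_s)
    else if (t < hyper)
      plateau_psi_mV + (min_psi_mV - plateau_psi_mV) *
        (t - onset) / decline_duration_s
    else if (t < t_rep) min_psi_mV
    else {
      base <- control_psi_mV + (min_psi_mV - control_psi_mV) *
        exp(-(t - t_rep) / rebound_tau_s)
      drift_t0 <- t_rep + 300
      drift <- if (t > drift_t0)
        (control_psi_mV - end_psi_mV) * (t - drift_t0) / (t_end - drift_t0)
      else 0
      base - drift
    }
  }
  fbl <- as.numeric(evaluate_curve(curve, psi))
  path <- ifelse(times >= hyper, path_step, 1)
  # cytochrome c reduction: low in control, high in ischemia, reversed fast
  red <- numeric(length(times))
  red_ctl <- 0.25; red_isc <- 1
  for (i in seq_along(times)) {
    t <- times[i]
    red[i] <- if (t < t_isc) red_ctl
    else if (t < t_rep)
      red_isc + (red_ctl - red_isc) * exp(-(t - t_isc) / drop_tau_s)
    else red_ctl + (red_isc - red_ctl) * exp(-(t - t_rep) / 10)
  }
  coefs <- data.frame(
    b_H = (1 - fbl) * amplitudes$b_total * path,
    b_L = fbl * amplitudes$b_total * path,
    c1 = amplitudes$c1 * path,
    c = amplitudes$c * red * path,
    slope = 0, intercept = 0.1)
  band_nm <- if (include_mb) c(535, 585) else c(540, 580)
  library <- make_reference_library(default_band_models(include_mb),
                                    band_nm = band_nm)
  if (include_mb) {
    mbo_frac <- numeric(length(times))
    for (i in seq_along(times)) {
      t <- times[i]
      mbo_frac[i] <- if (t < t_isc) 1
      else if (t < t_rep) exp(-(t - t_isc) / drop_tau_s)
      else 1 - exp(-(t - t_rep) / 10)
    }
    coefs$MbO <- amplitudes$mb * mbo_frac * path
    coefs$MbD <- amplitudes$mb * (1 - mbo_frac) * path
  }
  if (is.null(noise_sd_counts)) {
    noise_sd_counts <- if (snr_target > 0)
      noise_for_target_snr(coefs[1, ], library, band_nm = band_nm,
                           target_snr = snr_target)
    else 0
  }
  sim <- simulate_spectrum_series(coefs, library,
                                  noise_sd_counts = noise_sd_counts,
                                  seed = seed, times_s = times)
  truth <- sim$truth
  truth$psi_mV <- psi
  truth$path_mult <- path
  truth$cytc_amp <- coefs$c
  list(record = sim$record, truth = truth,
       events = list(secondary_onset_s = onset, hypercontracture_s = hyper),
       timeline = timeline, curve = curve, library = library,
       noise_sd_counts = noise_sd_counts)
}

#' Simulate a pulsatile effluent-flow trace
#'
#' Sinusoidal flow at the given heart rate, sampled at `fs` Hz, with
#' optional Gaussian noise; flow (and pulsation) is zero during an
#' ischemic window.
#'
#' @param duration_s trace length (s).
#' @param hr_bpm heart rate, default 300 bpm (5 Hz).
#' @param fs sampling rate, default 1000 Hz.
#' @param amplitude pulsation amplitude, default 5.
#' @param baseline mean flow, default 12 (ml/min scale).
#' @param noise_sd Gaussian noise SD, default 0.
#' @param ischemia_window optional `c(t0, t1)` of zero flow.
#' @param seed RNG seed.
#' @return `data.frame`: `time_s`, `flow`.
#' @export
simulate_flow_trace <- function(duration_s, hr_bpm = 300, fs = 1000,
                                amplitude = 5, baseline = 12, noise_sd = 0,
                                ischemia_window = NULL, seed = NULL) {
  t <- seq(1 / fs, duration_s, by = 1 / fs)
  flow <- baseline + amplitude * sin(2 * pi * hr_bpm / 60 * t)
  if (!is.null(ischemia_window))
    flow[t >= ischemia_window[1] & t <= ischemia_window[2]] <- 0
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    flow <- flow + stats::rnorm(length(flow), sd = noise_sd)
  }
  data.frame(time_s = t, flow = flow)
}

#' Generate calibration points from a true curve
#'
#' Emulates a set of condition means spanning the calibrated range:
#' potentials evenly spaced over the curve domain, fb_L from the true curve
#' plus Gaussian noise.
#'
#' @param curve true curve, default [default_true_curve()].
#' @param n number of condition means, default 23.
#' @param sigma_fbl fb_L noise SD, default 0.02.
#' @param seed RNG seed.
#' @return `data.frame(label, delta_psi_mV, fbl)`.
#' @export
simulate_calibration_points <- function(curve = default_true_curve(), n = 23,
                                        sigma_fbl = 0.02, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  psi <- seq(curve$domain_mV[1], curve$domain_mV[2], length.out = n)
  fbl <- as.numeric(evaluate_curve(curve, psi)) +
    if (sigma_fbl > 0) stats::rnorm(n, sd = sigma_fbl) else 0
  data.frame(label = sprintf("condition_%02d", seq_len(n)),
             delta_psi_mV = psi, fbl = pmin(1, pmax(0, fbl)))
}
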