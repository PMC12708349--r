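#' Construct an experiment timeline
#'
#' Ordered, contiguous, non-overlapping phases (typically control, ischemia,
#' reperfusion) with start/end times in seconds.
#'
#' @param phases `data.frame(name, start_s, end_s)`.
#' @return object of class `mitopsi_timeline`.
#' @export
experiment_timeline <- function(phases) {
  phases <- as.data.frame(phases)
  if (!all(c("name", "start_s", "end_s") %in% names(phases)))
    stop("phases needs name, start_s, end_s columns", call. = FALSE)
  if (any(phases$start_s >= phases$end_s))
    stop("each phase must have start < end", call. = FALSE)
  if (nrow(phases) > 1 &&
      any(abs(phases$start_s[-1] - phases$end_s[-nrow(phases)]) > 1e-9))
    stop("phases must be contiguous and non-overlapping", call. = FALSE)
  structure(list(phases = phases), class = "mitopsi_timeline")
}

#' Default ischemia-reperfusion timeline
#'
#' 10 min control, 20 min global ischemia, 20 min reperfusion.
#'
#' @param control_s,ischemia_s,reperfusion_s phase durations (s).
#' @return an [experiment_timeline()].
#' @export
default_ir_timeline <- function(control_s = 600, ischemia_s = 1200,
                                reperfusion_s = 1200) {
  experiment_timeline(data.frame(
    name = c("control", "ischemia", "reperfusion"),
    start_s = c(0, control_s, control_s + ischemia_s),
    end_s = c(control_s, control_s + ischemia_s,
              control_s + ischemia_s + reperfusion_s)))
}

phase_of <- function(timeline, time_s) {
  ph <- timeline$phases
  out <- rep(NA_character_, length(time_s))
  for (i in seq_len(nrow(ph)))
    out[time_s >= ph$start_s[i] & time_s <= ph$end_s[i]] <- ph$name[i]
  out
}

#' Run the full optical membrane-potential pipeline
#'
#' Composition of the whole inference chain on one record: absorbance over
#' the fit band, trailing rolling average of `window` consecutive spectra,
#' per-spectrum least-squares unmixing, signal-to-noise quality flagging,
#' fb_L, and censored inverse prediction of delta-psi through the
#' calibration curve. Deterministic for fixed inputs. The library and the
#' calibration curve must carry the same normalization stamp; a mismatch is
#' a configuration error because amplitudes would be on different scales.
#'
#' @param record a [raw_optical_record()].
#' @param library a [reference_library()].
#' @param curve a fitted calibration curve (`mitopsi_curve`).
#' @param timeline an [experiment_timeline()] (default 10/20/20 min
#'   control/ischemia/reperfusion).
#' @param window rolling-average window, default 4 spectra.
#' @param snr_threshold exclusion threshold, default 100.
#' @param band_nm optional fit band override (auto: 540-580, or 535-585 with
#'   myoglobin in the library).
#' @param margin censoring guard for [invert_curve()], default 0.01.
#' @return `data.frame` of class `mitopsi_series`: `time_s`, `phase`, `fbl`,
#'   `delta_psi_mV`, `censored`, `cytc_amp`, `b_L_amp`, `b_H_amp`, `snr`,
#'   `excluded`, `failed`. Excluded/failed rows carry no potential estimate.
#' @export
run_pipeline <- function(record, library, curve,
                         timeline = default_ir_timeline(), window = 4L,
                         snr_threshold = 100, band_nm = NULL, margin = 0.01) {
  stopifnot(inherits(record, "mitopsi_record"),
            inherits(library, "mitopsi_library"),
            inherits(curve, "mitopsi_curve"),
            inherits(timeline, "mitopsi_timeline"))
  if (!identical(library$normalization, curve$normalization))
    stop(sprintf("normalization mismatch: library '%s' vs calibration '%s'",
                 library$normalization, curve$normalization), call. = FALSE)
  model <- unmix_model(library, band_nm = band_nm,
                       snr_threshold = snr_threshold)
  res <- fit_series(record, model, window = window)
  res$phase <- phase_of(timeline, res$time_s)
  res$delta_psi_mV <- NA_real_
  res$censored <- NA_character_
  ok <- !res$excluded & !res$failed & !is.na(res$fbl)
  if (any(ok)) {
    inv <- invert_curve(curve, res$fbl[ok], margin = margin)
    res$delta_psi_mV[ok] <- inv$delta_psi_mV
    res$censored[ok] <- inv$censored
  }
  keep <- c("time_s", "phase", "fbl", "delta_psi_mV", "censored",
            "cytc_amp", "b_L_amp", "b_H_amp",
            intersect(c("MbO_amp", "MbD_amp"), names(res)),
            "ssr", "snr", "excluded", "failed")
  out <- res[, keep]
  attr(out, "band_nm") <- model$band_nm
  attr(out, "window") <- window
  class(out) <- c("mitopsi_series", class(out))
  out
}

# default checkpoint table mirroring the reported sampling times:
# control, 10 & 20 min of ischemia, 1, 2, 5, 10, 20 min of reperfusion
default_checkpoints <- function(timeline, window_s = 30) {
  ph <- timeline$phases
  get <- function(nm) ph[ph$name == nm, ]
  ctrl <- get("control"); isc <- get("ischemia"); rep_ <- get("reperfusion")
  cp <- rbind(
    data.frame(label = "control", time_s = ctrl$end_s - window_s),
    data.frame(label = c("ischemia 10 min", "ischemia 20 min"),
               time_s = isc$start_s + c(600, 1200 - window_s)),
    data.frame(label = paste("reperfusion", c(1, 2, 5, 10, 20), "min"),
               time_s = rep_$start_s + c(60, 120, 300, 600, 1200 - window_s)))
  cp <- cp[cp$time_s >= min(ph$start_s) & cp$time_s <= max(ph$end_s), ]
  cp$window_s <- window_s
  cp
}

#' Summarize the potential series at named checkpoints
#'
#' Means and standard deviations of fb_L, delta-psi and cytochrome c
#' amplitude over a window centred on each checkpoint. Censored potential
#' estimates are never averaged as plain numbers: a window containing any
#' censored-above rows yields a lower bound (`psi_censored = "above"`),
#' computed as the mean of bounds-and-points, which is itself a valid lower
#' bound; windows mixing both censoring directions report NA.
#'
#' @param series a [run_pipeline()] result.
#' @param timeline the [experiment_timeline()] used.
#' @param checkpoints `data.frame(label, time_s, window_s)`; default: end of
#'   control, 10/20 min of ischemia, 1/2/5/10/20 min of reperfusion with
#'   30-s windows.
#' @return `data.frame`: `label`, `t0_s`, `t1_s`, `fbl_mean`, `fbl_sd`,
#'   `psi_mean`, `psi_sd`, `psi_censored`, `cytc_mean`, `cytc_sd`, `n_used`,
#'   `n_excluded`, `missing`.
#' @export
phase_summary <- function(series, timeline, checkpoints = NULL) {
  if (is.null(checkpoints)) checkpoints <- default_checkpoints(timeline)
  rows <- lapply(seq_len(nrow(checkpoints)), function(i) {
    t0 <- checkpoints$time_s[i] - checkpoints$window_s[i] / 2
    t1 <- checkpoints$time_s[i] + checkpoints$window_s[i] / 2
    win <- series[series$time_s >= t0 & series$time_s <= t1, ]
    used <- win[!win$excluded & !win$failed, ]
    n_excl <- nrow(win) - nrow(used)
    if (nrow(used) == 0)
      return(data.frame(label = checkpoints$label[i], t0_s = t0, t1_s = t1,
                        fbl_mean = NA_real_, fbl_sd = NA_real_,
                        psi_mean = NA_real_, psi_sd = NA_real_,
                        psi_censored = NA_character_,
                        cytc_mean = NA_real_, cytc_sd = NA_real_,
                        n_used = 0L, n_excluded = n_excl, missing = TRUE))
    cens <- unique(stats::na.omit(used$censored))
    if (all(c("above", "below") %in% cens)) {
      psi_mean <- NA_real_; psi_sd <- NA_real_; psi_c <- "mixed"
    } else if ("above" %in% cens || "below" %in% cens) {
      psi_mean <- mean(used$delta_psi_mV)
      psi_sd <- NA_real_
      psi_c <- if ("above" %in% cens) "above" else "below"
    } else {
      psi_mean <- mean(used$delta_psi_mV)
      psi_sd <- stats::sd(used$delta_psi_mV)
      psi_c <- "none"
    }
    data.frame(label = checkpoints$label[i], t0_s = t0, t1_s = t1,
               fbl_mean = mean(used$fbl), fbl_sd = stats::sd(used$fbl),
               psi_mean = psi_mean, psi_sd = psi_sd, psi_censored = psi_c,
               cytc_mean = mean(used$cytc_amp), cytc_sd = stats::sd(used$cytc_amp),
               n_used = nrow(used), n_excluded = n_excl, missing = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Detect the secondary decline of membrane potential during ischemia
#'
#' During ischemia the potential first settles on a plateau, then -- when
#' glycolytic ATP can no longer sustain reverse operation of the ATP
#' synthase -- declines rapidly to a minimum coinciding with
#' hypercontracture. The detector smooths the potential trace with a
#' centred moving average (`smooth_s`), establishes the plateau (smoothed
#' slope within half the threshold for at least `plateau_s`), and reports
#' the earliest subsequent time at which the smoothed derivative stays
#' below `slope_threshold` for `sustain_s` consecutive samples, plus the
#' trace minimum.
#'
#' @param series a [run_pipeline()] result (or any data.frame with
#'   `time_s`, `delta_psi_mV`).
#' @param ischemia_window `c(t0, t1)` of the ischemic phase (s).
#' @param smooth_s centred smoothing window (s), default 61.
#' @param slope_threshold decline threshold (mV/s), default -0.15.
#' @param sustain_s consecutive seconds the slope must stay below threshold,
#'   default 5.
#' @param plateau_s minimum plateau duration before the event is eligible,
#'   default 120.
#' @return list: `event_time_s` (NA if no event), `min_value_mV`,
#'   `min_time_s`, `diagnostic`.
#' @export
detect_secondary_decline <- function(series, ischemia_window,
                                     smooth_s = 61, slope_threshold = -0.15,
                                     sustain_s = 5, plateau_s = 120) {
  sel <- series$time_s >= ischemia_window[1] &
    series$time_s <= ischemia_window[2] &
    !is.na(series$delta_psi_mV)
  if (!is.null(series$censored))
    sel <- sel & (is.na(series$censored) | series$censored == "none")
  t <- series$time_s[sel]; psi <- series$delta_psi_mV[sel]
  if (length(t) < 2 * smooth_s)
    stop("ischemia phase must cover at least twice the smoothing window",
         call. = FALSE)
  dt <- stats::median(diff(t))
  k <- max(3L, round(smooth_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(psi, rep(1 / k, k), sides = 2)
  h <- (k - 1L) / 2L
  n <- length(t)
  slope <- rep(NA_real_, n)
  idx <- (h + 1):(n - h)
  slope[idx] <- (sm[pmin(idx + h, n)] - sm[pmax(idx - h, 1)]) / (2 * h * dt)
  ok <- which(!is.na(slope))
  flat <- abs(slope) <= max(abs(slope_threshold) / 2, 1e-9)
  run <- 0L; plateau_end <- NA_integer_
  need <- round(plateau_s / dt)
  for (i in ok) {
    run <- if (isTRUE(flat[i])) run + 1L else 0L
    if (run >= need) { plateau_end <- i; break }
  }
  if (is.na(plateau_end))
    return(list(event_time_s = NA_real_, min_value_mV = min(psi),
                min_time_s = t[which.min(psi)],
                diagnostic = "no plateau found before decline"))
  sust <- max(1L, round(sustain_s / dt))
  run <- 0L; event <- NA_integer_
  for (i in ok[ok > plateau_end]) {
    run <- if (isTRUE(slope[i] < slope_threshold)) run + 1L else 0L
    if (run >= sust) { event <- i - sust + 1L; break }
  }
  list(event_time_s = if (is.na(event)) NA_real_ else t[event],
       min_value_mV = min(psi), min_time_s = t[which.min(psi)],
       diagnostic = if (is.na(event)) "no sustained decline after plateau"
       else "ok")
}

#' Heart rate from the pulsatile flow trace
#'
#' Each peak of the (near-sinusoidal) effluent flow wave is one beat; the
#' rate is the peak count per sliding minute, scaled to beats per minute.
#' A flat trace gives 0 bpm.
#'
#' @param time_s sample times (s); sampling must be at least 10x the beat
#'   frequency.
#' @param flow flow trace.
#' @param min_prominence minimum peak height above the trace median to count
#'   as a beat; default 20% of the amplitude (0 bpm for flat traces).
#' @param min_interval_s minimum inter-beat interval (s), default 0.1
#'   (600 bpm ceiling).
#' @param window_s sliding window (s), default 60; a shorter trace uses its
#'   full duration, scaled.
#' @return `data.frame`: `time_s` (window end), `bpm`.
#' @export
heart_rate_from_flow <- function(time_s, flow, min_prominence = NULL,
                                 min_interval_s = 0.1, window_s = 60) {
  fs <- 1 / stats::median(diff(time_s))
  amp <- (max(flow) - min(flow)) / 2
  if (is.null(min_prominence)) min_prominence <- 0.2 * amp
  centred <- flow - stats::median(flow)
  if (amp == 0 || max(centred) < min_prominence) {
    ends <- time_s[time_s >= min(time_s) + min(window_s, diff(range(time_s)))]
    if (!length(ends)) ends <- max(time_s)
    return(data.frame(time_s = ends, bpm = 0))
  }
  pk <- pracma::findpeaks(centred, minpeakheight = min_prominence,
                          minpeakdistance = max(1, round(min_interval_s * fs)))
  peak_t <- sort(time_s[pk[, 2]])
  dur <- length(time_s) / fs
  if (dur <= window_s) {
    return(data.frame(time_s = max(time_s),
                      bpm = length(peak_t) / dur * 60))
  }
  ends <- seq(min(time_s) + window_s, max(time_s), by = 1)
  bpm <- vapply(ends, function(e)
    sum(peak_t > e - window_s & peak_t <= e) * 60 / window_s, numeric(1))
  data.frame(time_s = ends, bpm = bpm)
}

#' Metabolite ratio computations
#'
#' `succinate_per_mg()`: tissue succinate from LC-MS/MS peak areas against a
#' stable-isotope internal standard, (area_analyte / area_IS) * IS amount /
#' tissue mass. `coq_percent_reduction()`: percent of the CoQ pool reduced,
#' 100 * QH2 / (QH2 + Q). `interpolate_timecourse()`: shape-preserving
#' piecewise-cubic (PCHIP) interpolation through sparse biochemical time
#' points; slopes are clamped at local extrema, so the curve passes through
#' every point and introduces no new local extrema between points.
#'
#' @param area_analyte,area_is LC-MS/MS peak areas (>= 0; IS area > 0).
#' @param is_amount_nmol internal standard amount (nmol).
#' @param tissue_mg tissue wet mass (mg).
#' @return nmol per mg tissue.
#' @export
succinate_per_mg <- function(area_analyte, area_is, is_amount_nmol, tissue_mg) {
  if (any(area_is <= 0) || any(tissue_mg <= 0))
    stop("internal standard area and tissue mass must be > 0", call. = FALSE)
  if (any(area_analyte < 0)) stop("areas must be >= 0", call. = FALSE)
  (area_analyte / area_is) * is_amount_nmol / tissue_mg
}

#' @rdname succinate_per_mg
#' @param area_qh2,area_q reduced and oxidized CoQ peak areas (sum > 0).
#' @export
coq_percent_reduction <- function(area_qh2, area_q) {
  if (any(area_qh2 < 0) || any(area_q < 0))
    stop("areas must be >= 0", call. = FALSE)
  if (any(area_qh2 + area_q == 0))
    stop("total CoQ pool area is zero", call. = FALSE)
  100 * area_qh2 / (area_qh2 + area_q)
}

#' @rdname succinate_per_mg
#' @param time_s,values sparse time points and measured values.
#' @param n number of interpolated samples, default 200.
#' @export
interpolate_timecourse <- function(time_s, values, n = 200) {
  if (length(time_s) != length(values) || length(time_s) < 2)
    stop("need matching time and value vectors of length >= 2", call. = FALSE)
  grid <- seq(min(time_s), max(time_s), length.out = n)
  data.frame(time_s = grid, value = pracma::pchip(time_s, values, grid))
}
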