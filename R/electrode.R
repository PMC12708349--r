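#' Construct a probe-electrode trace
#'
#' Voltage trace of a TPMP+-selective (or TPP+-selective; identical
#' treatment) electrode in a stirred mitochondrial suspension, together with
#' the probe addition schedule and bath constants needed for the Nernstian
#' analysis.
#'
#' @param time_s sample times (s), strictly increasing.
#' @param voltage_mV electrode voltage (mV).
#' @param additions `data.frame(time_s, amount_nmol)` of probe additions,
#'   non-decreasing in time.
#' @param bath_volume_ml bath volume (ml), default 5.5.
#' @param protein_mg total mitochondrial protein in the bath (mg).
#' @param total_probe_uM probe concentration after the final calibration
#'   addition (uM), default 2.17.
#' @return object of class `mitopsi_electrode_trace`.
#' @export
electrode_trace <- function(time_s, voltage_mV, additions,
                            bath_volume_ml = 5.5, protein_mg,
                            total_probe_uM = 2.17) {
  if (length(time_s) != length(voltage_mV))
    stop("time_s and voltage_mV must have equal length", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing", call. = FALSE)
  additions <- as.data.frame(additions)
  if (!all(c("time_s", "amount_nmol") %in% names(additions)))
    stop("additions needs time_s and amount_nmol columns", call. = FALSE)
  if (is.unsorted(additions$time_s))
    stop("additions must be non-decreasing in time", call. = FALSE)
  if (bath_volume_ml <= 0 || protein_mg <= 0)
    stop("bath volume and protein load must be > 0", call. = FALSE)
  structure(list(time_s = as.numeric(time_s),
                 voltage_mV = as.numeric(voltage_mV),
                 additions = additions, bath_volume_ml = bath_volume_ml,
                 protein_mg = protein_mg, total_probe_uM = total_probe_uM),
            class = "mitopsi_electrode_trace")
}

#' Calibrate the electrode from stepwise probe additions
#'
#' After each addition the external probe concentration is known from the
#' cumulative amount added and the bath volume; the plateau voltage is the
#' mean over a settling-excluded window running to the next addition (or to
#' `cal_end_s`). A least-squares line V = intercept + slope * log10(c) is
#' fit through the plateau pairs; for an ideal Nernstian electrode the slope
#' is about 59 mV per decade at room temperature.
#'
#' @param trace an [electrode_trace()].
#' @param settle_s settling time excluded after each addition (s), default 10.
#' @param cal_end_s end of the calibration segment (s); default: last
#'   addition time plus the median inter-addition gap.
#' @return object of class `mitopsi_electrode_cal` with `slope_mV_per_decade`,
#'   `intercept_mV`, `r_squared` and the plateau table used.
#' @export
calibrate_electrode <- function(trace, settle_s = 10, cal_end_s = NULL) {
  stopifnot(inherits(trace, "mitopsi_electrode_trace"))
  add <- trace$additions
  if (nrow(add) < 2)
    stop("insufficient calibration: need at least 2 addition plateaus",
         call. = FALSE)
  if (is.null(cal_end_s)) {
    gap <- if (nrow(add) > 1) stats::median(diff(add$time_s)) else 60
    cal_end_s <- add$time_s[nrow(add)] + gap
  }
  ends <- c(add$time_s[-1], cal_end_s)
  conc <- cumsum(add$amount_nmol) / trace$bath_volume_ml   # uM
  plateau <- lapply(seq_len(nrow(add)), function(i) {
    sel <- trace$time_s >= add$time_s[i] + settle_s & trace$time_s < ends[i]
    if (!any(sel)) return(NULL)
    data.frame(conc_uM = conc[i], voltage_mV = mean(trace$voltage_mV[sel]),
               n = sum(sel))
  })
  plateau <- do.call(rbind, plateau)
  if (is.null(plateau) || nrow(plateau) < 2)
    stop("insufficient calibration: fewer than 2 usable plateaus", call. = FALSE)
  fit <- stats::lm(voltage_mV ~ log10(conc_uM), data = plateau)
  tss <- sum((plateau$voltage_mV - mean(plateau$voltage_mV))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  if (is.unsorted(plateau$voltage_mV) && is.unsorted(rev(plateau$voltage_mV)))
    warning(sprintf("non-monotone plateau voltages (r^2 = %.4f)", r2),
            call. = FALSE)
  structure(list(slope_mV_per_decade = unname(stats::coef(fit)[2]),
                 intercept_mV = unname(stats::coef(fit)[1]),
                 r_squared = r2, plateaus = plateau),
            class = "mitopsi_electrode_cal")
}

#' @export
print.mitopsi_electrode_cal <- function(x, ...) {
  cat(sprintf("<electrode calibration: %.2f mV/decade, intercept %.2f mV, r^2 %.5f, %d plateaus>\n",
              x$slope_mV_per_decade, x$intercept_mV, x$r_squared,
              nrow(x$plateaus)))
  invisible(x)
}

#' Nernst potential from a probe concentration ratio
#'
#' delta-psi = 61.5 * log10(c_in / c_out) mV, the monovalent-cation Nernst
#' relation at 37 C with the constant as conventionally printed.
#'
#' @param c_in,c_out matrix and external free probe concentrations (> 0,
#'   same units). Vectorized.
#' @param slope_mV mV per decade, default 61.5.
#' @return membrane potential in mV.
#' @export
nernst_potential <- function(c_in, c_out, slope_mV = 61.5) {
  if (any(c_in <= 0) || any(c_out <= 0))
    stop("concentrations must be positive", call. = FALSE)
  slope_mV * log10(c_in / c_out)
}

#' Convert an electrode voltage trace to a membrane-potential time series
#'
#' Per sample: external concentration c_out = 10^((V - intercept)/slope)
#' (uM); probe uptake = (total - c_out) * bath volume (nmol); matrix free
#' concentration c_in = uptake / protein * binding correction, in
#' nmol per ul, i.e. mM; and delta-psi from [nernst_potential()] with c_out
#' converted to mM so both sides of the ratio share units. Small negative
#' uptakes (within `tolerance` of the total probe amount) are treated as
#' noise, clipped to zero and flagged; larger ones are an error.
#'
#' @param trace an [electrode_trace()].
#' @param cal a [calibrate_electrode()] result.
#' @param binding_mg_per_uL empirical probe binding correction
#'   (mg protein per ul), default 0.17.
#' @param tolerance tolerated negative uptake as a fraction of total probe,
#'   default 0.02.
#' @return `data.frame`: `time_s`, `c_out_uM`, `uptake_nmol`, `c_in_mM`,
#'   `delta_psi_mV` (NA where uptake is zero/clipped), `clipped`,
#'   `out_of_range` (voltage beyond calibrated range +- 1 decade).
#' @export
trace_to_potential <- function(trace, cal, binding_mg_per_uL = 0.17,
                               tolerance = 0.02) {
  stopifnot(inherits(trace, "mitopsi_electrode_trace"),
            inherits(cal, "mitopsi_electrode_cal"))
  total <- trace$total_probe_uM
  c_out <- 10^((trace$voltage_mV - cal$intercept_mV) / cal$slope_mV_per_decade)
  vr <- range(cal$plateaus$voltage_mV)
  out_of_range <- trace$voltage_mV < vr[1] - abs(cal$slope_mV_per_decade) |
    trace$voltage_mV > vr[2] + abs(cal$slope_mV_per_decade)
  uptake <- (total - c_out) * trace$bath_volume_ml   # uM * ml = nmol
  neg <- uptake < 0
  # isolated noise excursions are clipped and flagged; a systematic excess
  # (many samples beyond tolerance) indicates miscalibration and is fatal
  beyond <- uptake < -tolerance * total * trace$bath_volume_ml
  if (mean(beyond) > 0.01)
    stop(sprintf(
      "negative probe uptake beyond tolerance in %.1f%% of samples: check calibration or total_probe_uM",
      100 * mean(beyond)), call. = FALSE)
  uptake[neg] <- 0
  c_in <- uptake / trace$protein_mg * binding_mg_per_uL   # nmol/ul = mM
  psi <- rep(NA_real_, length(c_in))
  ok <- c_in > 0 & c_out > 0
  psi[ok] <- nernst_potential(c_in[ok], c_out[ok] * 1e-3)
  data.frame(time_s = trace$time_s, c_out_uM = c_out, uptake_nmol = uptake,
             c_in_mM = c_in, delta_psi_mV = psi, clipped = neg,
             out_of_range = out_of_range)
}

#' Mean and dispersion over a steady-state window
#'
#' @param time_s sample times (s).
#' @param values scalar trace.
#' @param window `c(t0, t1)` time interval (inclusive), within the series.
#' @return list: `mean`, `sd`, `n`.
#' @export
steady_state_mean <- function(time_s, values, window) {
  sel <- time_s >= window[1] & time_s <= window[2]
  if (sum(sel) < 3)
    stop("steady-state window must contain at least 3 samples", call. = FALSE)
  list(mean = mean(values[sel]), sd = stats::sd(values[sel]), n = sum(sel))
}
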