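#' Construct a single optical spectrum
#'
#' A spectrum is a wavelength-indexed optical trace: either raw detector
#' counts (`role = "intensity"`), an optical density trace
#' (`role = "absorbance"`), or a reduced-chromophore reference
#' (`role = "reference"`). The role is fixed at construction.
#'
#' @param wavelengths_nm strictly increasing numeric wavelength grid (nm).
#' @param values finite numeric values, one per wavelength.
#' @param role one of `"intensity"`, `"absorbance"`, `"reference"`.
#' @param name optional label.
#' @return object of class `mitopsi_spectrum`.
#' @export
spectrum <- function(wavelengths_nm, values,
                     role = c("intensity", "absorbance", "reference"),
                     name = "") {
  role <- match.arg(role)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths_nm and values must have equal length", call. = FALSE)
  if (any(!is.finite(wavelengths_nm)) || any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("spectrum values must be finite", call. = FALSE)
  structure(
    list(wavelengths_nm = wavelengths_nm, values = values,
         role = role, name = name),
    class = "mitopsi_spectrum")
}

#' @export
print.mitopsi_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s' [%s], %d points, %.1f-%.1f nm>\n",
              x$name, x$role, length(x$values),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Construct a raw multi-wavelength optical record
#'
#' Bundles one acquisition session: the incident-light spectrum I0 recorded
#' without sample, the spectrometer dark current D, and a timestamped series
#' of transmitted-light spectra T, all on one wavelength grid.
#'
#' @param wavelengths_nm strictly increasing wavelength grid (nm).
#' @param incident incident-light counts I0(lambda).
#' @param dark dark-current counts D(lambda).
#' @param transmissions matrix of transmitted counts, one column per
#'   timepoint (`length(wavelengths_nm)` rows).
#' @param times_s strictly increasing timestamps (s), one per column.
#' @param sample_period_s seconds per spectrum (> 0), default 1.
#' @return object of class `mitopsi_record`.
#' @export
raw_optical_record <- function(wavelengths_nm, incident, dark, transmissions,
                               times_s = NULL, sample_period_s = 1) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  n <- length(wavelengths_nm)
  transmissions <- as.matrix(transmissions)
  if (is.null(times_s))
    times_s <- seq_len(ncol(transmissions)) * sample_period_s
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (length(incident) != n || length(dark) != n || nrow(transmissions) != n)
    stop("incident, dark and transmissions must share the wavelength grid length",
         call. = FALSE)
  if (length(times_s) != ncol(transmissions) || any(diff(times_s) <= 0))
    stop("timestamps must be strictly increasing, one per transmission spectrum",
         call. = FALSE)
  if (!is.numeric(sample_period_s) || sample_period_s <= 0)
    stop("sample_period_s must be > 0", call. = FALSE)
  structure(
    list(wavelengths_nm = wavelengths_nm,
         incident = as.numeric(incident), dark = as.numeric(dark),
         transmissions = transmissions, times_s = as.numeric(times_s),
         sample_period_s = sample_period_s),
    class = "mitopsi_record")
}

#' @export
print.mitopsi_record <- function(x, ...) {
  cat(sprintf("<optical record: %d wavelengths (%.1f-%.1f nm), %d spectra @ %.3g s>\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), ncol(x$transmissions), x$sample_period_s))
  invisible(x)
}

# band subset indices; band = c(lo, hi) in nm, NULL = full grid
band_index <- function(wavelengths_nm, band_nm) {
  if (is.null(band_nm)) return(seq_along(wavelengths_nm))
  which(wavelengths_nm >= band_nm[1] & wavelengths_nm <= band_nm[2])
}

#' Compute absorbance from a raw optical record
#'
#' A(lambda) = log10((I0 - D) / (T - D)): the log10-transformed ratio of
#' dark-corrected incident to dark-corrected transmitted light. Dark current
#' is subtracted from both streams so that an empty light path gives exactly
#' A = 0.
#'
#' @param record a [raw_optical_record()].
#' @param index time index of the transmission spectrum (column).
#' @param band_nm optional `c(lo, hi)` wavelength band to restrict to; the
#'   positivity precondition is enforced only inside this band.
#' @return absorbance [spectrum()].
#' @export
compute_absorbance <- function(record, index = 1L, band_nm = NULL) {
  stopifnot(inherits(record, "mitopsi_record"))
  idx <- band_index(record$wavelengths_nm, band_nm)
  i0 <- record$incident[idx] - record$dark[idx]
  tr <- record$transmissions[idx, index] - record$dark[idx]
  bad <- which(i0 <= 0 | tr <= 0)
  if (length(bad)) {
    lam <- record$wavelengths_nm[idx][bad]
    stop(sprintf(
      "nonpositive dark-corrected intensity at %d wavelength(s): %s%s",
      length(bad), paste(format(utils::head(lam, 5), digits = 6), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""), call. = FALSE)
  }
  spectrum(record$wavelengths_nm[idx], log10(i0 / tr), role = "absorbance",
           name = sprintf("t=%g s", record$times_s[index]))
}

# absorbance for all timepoints at once; returns n_wl x n_t matrix
absorbance_matrix <- function(record, band_nm = NULL) {
  idx <- band_index(record$wavelengths_nm, band_nm)
  i0 <- record$incident[idx] - record$dark[idx]
  tr <- record$transmissions[idx, , drop = FALSE] - record$dark[idx]
  if (any(i0 <= 0) || any(tr <= 0))
    stop("nonpositive dark-corrected intensity in requested band", call. = FALSE)
  a <- log10(i0 / tr)
  rownames(a) <- NULL
  a
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; values at shared grid points are unchanged.
#' Extrapolation outside the source support is refused.
#'
#' @param spec a [spectrum()].
#' @param grid target wavelength grid (nm), within the source support.
#' @return resampled [spectrum()] with the same role and name.
#' @export
resample_to_grid <- function(spec, grid) {
  stopifnot(inherits(spec, "mitopsi_spectrum"))
  grid <- as.numeric(grid)
  rng <- range(spec$wavelengths_nm)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop(sprintf("target grid [%.3f, %.3f] nm extends beyond source support [%.3f, %.3f] nm",
                 min(grid), max(grid), rng[1], rng[2]), call. = FALSE)
  vals <- stats::approx(spec$wavelengths_nm, spec$values, xout = grid,
                        method = "linear", ties = "ordered")$y
  spectrum(grid, vals, role = spec$role, name = spec$name)
}

#' Trailing rolling average
#'
#' Causal (trailing-window) mean used before spectral fitting: each output
#' sample is the mean of the `window` most recent input samples, stamped with
#' the timestamp of the last sample in the window. Works on a numeric vector
#' (scalar trace) or a matrix whose columns are successive spectra.
#'
#' @param x numeric vector, or matrix with one column per timepoint.
#' @param window integer window length >= 1 and <= series length.
#' @return vector of length `N - window + 1`, or matrix with that many columns.
#' @export
rolling_average <- function(x, window) {
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (window > n)
    stop(sprintf("window (%d) exceeds series length (%d)", window, n),
         call. = FALSE)
  if (is.matrix(x)) {
    out <- matrix(0, nrow(x), n - window + 1L)
    for (j in seq_len(n - window + 1L))
      out[, j] <- rowMeans(x[, j:(j + window - 1L), drop = FALSE])
    out
  } else {
    vapply(seq_len(n - window + 1L),
           function(j) mean(x[j:(j + window - 1L)]), numeric(1))
  }
}

#' Derive a reference spectrum by fractional subtraction
#'
#' result = minuend - fraction * subtrahend. This is the arithmetic used to
#' isolate pure reduced references from composite measurements: e.g. the
#' reduced cytochrome c1 reference is obtained by subtracting 66% of the
#' oxidized spectrum from the ascorbate-reduced spectrum, and the b_L
#' reference is an anoxia-minus-uncoupler difference (fraction 1).
#'
#' @param minuend,subtrahend spectra on a shared grid.
#' @param fraction scalar in `[0, 1]`; 1 gives a plain difference.
#' @return derived [spectrum()] with role `"reference"`.
#' @export
derive_reference <- function(minuend, subtrahend, fraction = 1) {
  stopifnot(inherits(minuend, "mitopsi_spectrum"),
            inherits(subtrahend, "mitopsi_spectrum"))
  if (!isTRUE(all.equal(minuend$wavelengths_nm, subtrahend$wavelengths_nm,
                        tolerance = 0)))
    stop("wavelength grids differ; resample with resample_to_grid() first",
         call. = FALSE)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  spectrum(minuend$wavelengths_nm,
           minuend$values - fraction * subtrahend$values,
           role = "reference", name = minuend$name)
}

#' Heme quantification configuration
#'
#' Beer-Lambert parameters for quantifying cytochrome a + a3 from the
#' reduced-minus-oxidized absorbance difference at 605 nm.
#'
#' @param epsilon_mM_cm extinction coefficient (mM^-1 cm^-1), default 12.
#' @param wavelength_nm measurement wavelength, default 605.
#' @param pathlength_cm optical path length (cm), default 1.
#' @return list of class `mitopsi_heme_quant_config`.
#' @export
heme_quant_config <- function(epsilon_mM_cm = 12, wavelength_nm = 605,
                              pathlength_cm = 1) {
  if (epsilon_mM_cm <= 0 || wavelength_nm <= 0 || pathlength_cm <= 0)
    stop("all heme quantification parameters must be positive", call. = FALSE)
  structure(list(epsilon_mM_cm = epsilon_mM_cm, wavelength_nm = wavelength_nm,
                 pathlength_cm = pathlength_cm),
            class = "mitopsi_heme_quant_config")
}

#' Quantify heme concentration from a delta-absorbance
#'
#' c = dA / (epsilon * path), Beer-Lambert. Returned in mM; multiply by 1000
#' for nmol ml^-1. A negative delta-absorbance yields a warning-flagged
#' negative concentration rather than an error.
#'
#' @param delta_A reduced-minus-oxidized absorbance at the config wavelength.
#' @param config a [heme_quant_config()].
#' @return concentration in mM (numeric, vectorized over `delta_A`).
#' @export
quantify_heme_concentration <- function(delta_A, config = heme_quant_config()) {
  stopifnot(inherits(config, "mitopsi_heme_quant_config"))
  conc <- delta_A / (config$epsilon_mM_cm * config$pathlength_cm)
  if (any(delta_A < 0))
    warning("negative delta-absorbance: returning negative concentration",
            call. = FALSE)
  conc
}
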