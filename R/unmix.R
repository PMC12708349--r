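#' Specify a spectral unmixing model
#'
#' Describes the linear decomposition of an alpha-band absorbance spectrum
#' into reduced-chromophore contributions plus a straight line:
#'
#'   A(lambda) = a*b_H + b*b_L + c*c1 + d*cytc (+ MbO, MbD) + e*lambda + f
#'
#' The line absorbs residual scattering and the weak, spectrally flat
#' absorbance of oxidized cytochromes. The default fit band is 540-580 nm;
#' when myoglobin references are in the library the band widens to
#' 535-585 nm automatically.
#'
#' @param library a [reference_library()] (quartet for Mb-free tissue,
#'   quartet + MbO/MbD for wild type).
#' @param band_nm fit interval; defaults to `c(540, 580)` or `c(535, 585)`
#'   when Mb references are present.
#' @param include_baseline include the line term (default TRUE).
#' @param nonneg constrain chromophore coefficients to be nonnegative
#'   (default FALSE; the baseline stays unconstrained).
#' @param snr_threshold exclusion threshold for the signal-to-noise
#'   statistic, default 100 (convention-sensitive: scales with grid density).
#' @return object of class `mitopsi_unmix_model`.
#' @export
unmix_model <- function(library, band_nm = NULL, include_baseline = TRUE,
                        nonneg = FALSE, snr_threshold = 100) {
  stopifnot(inherits(library, "mitopsi_library"))
  has_mb <- all(c("MbO", "MbD") %in% colnames(library$refs))
  if (is.null(band_nm)) band_nm <- if (has_mb) c(535, 585) else c(540, 580)
  if (band_nm[1] < min(library$grid) || band_nm[2] > max(library$grid))
    stop("fit band must lie within the library grid", call. = FALSE)
  if (ncol(library$refs) < 2)
    stop("need at least two chromophore references", call. = FALSE)
  if (snr_threshold <= 0) stop("snr_threshold must be > 0", call. = FALSE)
  structure(list(library = library, band_nm = as.numeric(band_nm),
                 include_baseline = include_baseline, nonneg = nonneg,
                 snr_threshold = snr_threshold),
            class = "mitopsi_unmix_model")
}

# design matrix over band: chromophore columns then (lambda, 1) if baseline
unmix_design <- function(model, grid = NULL) {
  lib <- model$library
  if (!is.null(grid)) lib <- align_library(lib, grid)
  idx <- band_index(lib$grid, model$band_nm)
  X <- lib$refs[idx, , drop = FALSE]
  if (model$include_baseline)
    X <- cbind(X, slope = lib$grid[idx], intercept = 1)
  list(X = X, idx = idx, lambda = lib$grid[idx], lib = lib)
}

#' Fit the unmixing model to an absorbance spectrum
#'
#' The model is linear in its coefficients, so the least-squares solution is
#' computed directly by QR decomposition (with the wavelength column centred
#' and scaled internally for numerical stability, then mapped back to the
#' slope-per-nm / intercept parametrization). A rank-deficient design (for
#' example duplicated references) is refused, with the condition number
#' reported, rather than silently regularized.
#'
#' @param absorbance an absorbance [spectrum()] covering the fit band.
#' @param model an [unmix_model()] whose library is aligned (or alignable)
#'   to the spectrum grid.
#' @return object of class `mitopsi_unmix_fit`: named `coefficients`
#'   (chromophores plus `slope`, `intercept`), `component_spectra`
#'   (coefficient x reference at each band wavelength), `fitted`,
#'   `residuals`, `ssr`, and placeholders `snr`/`excluded` filled by
#'   [compute_snr_and_flag()].
#' @export
fit_spectrum <- function(absorbance, model) {
  stopifnot(inherits(absorbance, "mitopsi_spectrum"),
            inherits(model, "mitopsi_unmix_model"))
  if (absorbance$role != "absorbance")
    stop("fit_spectrum expects an absorbance spectrum", call. = FALSE)
  d <- unmix_design(model, grid = absorbance$wavelengths_nm)
  y <- absorbance$values[d$idx]
  fit_band_vector(y, d, model)
}

# core solver on a band-restricted absorbance vector
fit_band_vector <- function(y, d, model) {
  X <- d$X
  p <- ncol(X)
  n_chrom <- p - if (model$include_baseline) 2L else 0L
  # scaled copy for solving
  Xs <- X
  if (model$include_baseline) {
    mu <- mean(d$lambda); sdl <- stats::sd(d$lambda)
    Xs[, "slope"] <- (d$lambda - mu) / sdl
  }
  qrX <- qr(Xs)
  if (qrX$rank < p) {
    kap <- kappa(X, exact = TRUE)
    stop(sprintf("rank-deficient unmixing design (rank %d < %d, condition number %.3g)",
                 qrX$rank, p, kap), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  if (model$nonneg) beta <- nnls_refit(Xs, y, n_chrom)
  if (model$include_baseline) {
    e <- beta["slope"] / sdl
    f <- beta["intercept"] - e * mu
    beta["slope"] <- e; beta["intercept"] <- f
  }
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  comp <- sweep(X[, seq_len(n_chrom), drop = FALSE], 2,
                beta[seq_len(n_chrom)], "*")
  structure(
    list(coefficients = beta, component_spectra = comp,
         lambda = d$lambda, data = y, fitted = fitted, residuals = resid,
         ssr = sum(resid^2), snr = NA_real_, excluded = NA,
         band_nm = model$band_nm,
         peak_od = apply(d$X[, seq_len(n_chrom), drop = FALSE], 2, max)),
    class = "mitopsi_unmix_fit")
}

# nonnegative chromophore coefficients by iterated clamp-and-refit
# (baseline columns stay free); adequate for the optional noisy-data mode
nnls_refit <- function(X, y, n_chrom) {
  active <- rep(TRUE, ncol(X))
  repeat {
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    if (any(active))
      beta[active] <- qr.coef(qr(X[, active, drop = FALSE]), y)
    neg <- active & beta < 0 & seq_along(beta) <= n_chrom
    if (!any(neg)) return(beta)
    active[neg] <- FALSE
  }
}

#' @export
print.mitopsi_unmix_fit <- function(x, ...) {
  cat("<unmix fit>\n  coefficients:\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  ssr = %.3g, snr = %.3g, excluded = %s\n",
              x$ssr, x$snr, x$excluded))
  invisible(x)
}

#' Compute the fraction of reduced heme b_L
#'
#' fb_L = b_L / (b_L + b_H), computed from the peak-OD amplitudes of the two
#' b hemes. The amplitude of a chromophore is its fit coefficient multiplied
#' by the peak optical density of its reference within the fit band -- equal
#' to the coefficient itself under the unit-peak library normalization.
#' Because both hemes scale identically with optical path length, fb_L is
#' invariant to tissue geometry.
#'
#' @param fit a [fit_spectrum()] result.
#' @return list of class `mitopsi_fbl`: `value`, `b_L_amp`, `b_H_amp`, and
#'   `negative_amplitude` QC flag.
#' @export
compute_fbl <- function(fit) {
  stopifnot(inherits(fit, "mitopsi_unmix_fit"))
  bl <- unname(fit$coefficients["b_L"] * fit$peak_od["b_L"])
  bh <- unname(fit$coefficients["b_H"] * fit$peak_od["b_H"])
  if (bl + bh == 0)
    stop("fb_L undefined: both b-heme amplitudes are zero", call. = FALSE)
  structure(list(value = bl / (bl + bh), b_L_amp = bl, b_H_amp = bh,
                 negative_amplitude = (bl < 0 || bh < 0)),
            class = "mitopsi_fbl")
}

#' Compute the signal-to-noise statistic and exclusion flag
#'
#' snr = (sum over band wavelengths of the reconstructed b_L, b_H, c1 and
#' cytochrome c component absorbances) / (sum of squared residuals). The
#' numerator covers exactly the four named chromophores (baseline and
#' myoglobin terms are not counted). Data points whose statistic falls below
#' the threshold are flagged for exclusion. Zero residuals give an infinite
#' statistic (never excluded).
#'
#' @param fit a [fit_spectrum()] result.
#' @param model the [unmix_model()] used (supplies the threshold).
#' @return the fit, with `snr` and `excluded` filled in.
#' @export
compute_snr_and_flag <- function(fit, model) {
  stopifnot(inherits(fit, "mitopsi_unmix_fit"),
            inherits(model, "mitopsi_unmix_model"))
  quartet <- intersect(c("b_H", "b_L", "c1", "c"),
                       colnames(fit$component_spectra))
  num <- sum(fit$component_spectra[, quartet])
  fit$snr <- if (fit$ssr == 0) Inf else max(0, num / fit$ssr)
  fit$excluded <- fit$snr < model$snr_threshold
  fit
}

#' Fit an unmixing model to every timepoint of a record
#'
#' Absorbance is computed over the fit band, a trailing rolling average of
#' `window` consecutive spectra is taken, and each averaged spectrum is fit
#' and quality-flagged. A row whose fit fails is flagged, not fatal.
#'
#' @param record a [raw_optical_record()].
#' @param model an [unmix_model()].
#' @param window rolling-average window (spectra), default 1 (no averaging).
#' @return tidy `data.frame`: `time_s`, one column per coefficient,
#'   `b_L_amp`, `b_H_amp`, `fbl`, `cytc_amp`, Mb amplitudes if fit, `ssr`,
#'   `snr`, `excluded`, `failed`.
#' @export
fit_series <- function(record, model, window = 1L) {
  stopifnot(inherits(record, "mitopsi_record"))
  if (ncol(record$transmissions) < window)
    stop("record shorter than rolling window", call. = FALSE)
  d <- unmix_design(model, grid = record$wavelengths_nm)
  amat <- absorbance_matrix(record, band_nm = model$band_nm)
  amat <- rolling_average(amat, window)
  times <- record$times_s[seq.int(window, length(record$times_s))]
  has_mb <- all(c("MbO", "MbD") %in% colnames(d$X))
  rows <- lapply(seq_len(ncol(amat)), function(j) {
    tryCatch({
      fit <- fit_band_vector(amat[, j], d, model)
      fit <- compute_snr_and_flag(fit, model)
      fbl <- compute_fbl(fit)
      co <- fit$coefficients
      row <- data.frame(time_s = times[j], t(co),
                        b_L_amp = fbl$b_L_amp, b_H_amp = fbl$b_H_amp,
                        fbl = fbl$value,
                        cytc_amp = unname(co["c"] * fit$peak_od["c"]),
                        ssr = fit$ssr, snr = fit$snr,
                        excluded = fit$excluded, failed = FALSE)
      if (has_mb) {
        row$MbO_amp <- unname(co["MbO"] * fit$peak_od["MbO"])
        row$MbD_amp <- unname(co["MbD"] * fit$peak_od["MbD"])
      }
      row
    }, error = function(e) {
      data.frame(time_s = times[j], fbl = NA_real_, ssr = NA_real_,
                 snr = NA_real_, excluded = TRUE, failed = TRUE)
    })
  })
  allcols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(allcols, names(r))) r[[cn]] <- NA
    r[allcols]
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
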