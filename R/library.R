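#' Construct a reduced-chromophore reference library
#'
#' A named set of reduced-chromophore reference spectra on a common
#' wavelength grid, normalized so that every member has unit peak optical
#' density within the fit band. The library must always contain the quartet
#' b_H, b_L, c1, c; oxygenated/deoxygenated myoglobin (MbO, MbD) are
#' optional. Empirically collected references have arbitrary absolute OD, so
#' the unit-peak convention is fixed here and stamped into the object;
#' calibration and application must share one library (and one stamp).
#'
#' @param grid common wavelength grid (nm), strictly increasing.
#' @param refs matrix of reference spectra, one named column per chromophore,
#'   or a named list of [spectrum()] objects (resampled onto `grid`).
#' @param band_nm fit band `c(lo, hi)` within which peaks are normalized to 1.
#' @param peak_nm optional named numeric vector of nominal alpha-band peak
#'   wavelengths; defaults filled from [default_peaks()] where known.
#' @param normalize normalize to unit peak in band (default TRUE).
#' @return object of class `mitopsi_library`.
#' @export
reference_library <- function(grid, refs, band_nm = c(540, 580),
                              peak_nm = NULL, normalize = TRUE) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0))
    stop("library grid must be strictly increasing", call. = FALSE)
  if (is.list(refs) && !is.data.frame(refs)) {
    refs <- vapply(refs, function(s) {
      stopifnot(inherits(s, "mitopsi_spectrum"))
      resample_to_grid(s, grid)$values
    }, numeric(length(grid)))
  }
  refs <- as.matrix(refs)
  if (is.null(colnames(refs)) || anyNA(colnames(refs)))
    stop("reference columns must be named", call. = FALSE)
  required <- c("b_H", "b_L", "c1", "c")
  if (!all(required %in% colnames(refs)))
    stop("library must contain the quartet b_H, b_L, c1, c", call. = FALSE)
  if (nrow(refs) != length(grid))
    stop("reference spectra must share the library grid", call. = FALSE)
  idx <- band_index(grid, band_nm)
  if (!length(idx)) stop("fit band outside library grid", call. = FALSE)
  if (normalize) {
    peaks <- apply(refs[idx, , drop = FALSE], 2, max)
    if (any(peaks <= 0))
      stop("cannot unit-peak normalize: nonpositive peak in fit band",
           call. = FALSE)
    refs <- sweep(refs, 2, peaks, "/")
  }
  if (is.null(peak_nm)) {
    known <- default_peaks()
    peak_nm <- known[intersect(colnames(refs), names(known))]
  }
  lib <- structure(
    list(grid = grid, refs = refs, band_nm = as.numeric(band_nm),
         normalization = if (normalize) "unit_peak" else "raw",
         peak_nm = peak_nm),
    class = "mitopsi_library")
  validate_library(lib)
  lib
}

#' Nominal alpha-band peak wavelengths (nm)
#'
#' Reduced cytochrome c peaks at 550 nm, c1 at 552 nm, heme b_H at 562 nm;
#' the b_L reference shows its main feature at 566 nm with a shoulder at
#' 558 nm (the nominal b_L peak is often quoted at 564 nm).
#'
#' @return named numeric vector.
#' @export
default_peaks <- function() {
  c(c = 550, c1 = 552, b_H = 562, b_L = 566, MbO = 580, MbD = 556)
}

#' Validate reference-library invariants
#'
#' Checks the required quartet, grid alignment, and (for unit-peak
#' normalization) that every member's maximum inside the fit band is exactly
#' 1 within 1e-12.
#'
#' @param lib a [reference_library()].
#' @return `lib`, invisibly; errors on violation.
#' @export
validate_library <- function(lib) {
  stopifnot(inherits(lib, "mitopsi_library"))
  if (!all(c("b_H", "b_L", "c1", "c") %in% colnames(lib$refs)))
    stop("library lost its required quartet", call. = FALSE)
  if (lib$normalization == "unit_peak") {
    idx <- band_index(lib$grid, lib$band_nm)
    peaks <- apply(lib$refs[idx, , drop = FALSE], 2, max)
    if (any(abs(peaks - 1) > 1e-12))
      stop("unit-peak normalization violated: peak OD in band is not 1",
           call. = FALSE)
  }
  invisible(lib)
}

#' @export
print.mitopsi_library <- function(x, ...) {
  cat(sprintf("<reference library: %s; %d grid points; band %.0f-%.0f nm; %s>\n",
              paste(colnames(x$refs), collapse = ", "), length(x$grid),
              x$band_nm[1], x$band_nm[2], x$normalization))
  invisible(x)
}

#' Align a reference library onto an experimental wavelength grid
#'
#' References are resampled (linear interpolation) onto the data grid --
#' never the reverse -- and re-normalized to unit peak on the new grid.
#'
#' @param lib a [reference_library()].
#' @param grid target wavelength grid (nm).
#' @return a [reference_library()] on `grid`.
#' @export
align_library <- function(lib, grid) {
  stopifnot(inherits(lib, "mitopsi_library"))
  grid <- as.numeric(grid)
  if (isTRUE(all.equal(lib$grid, grid, tolerance = 0))) return(lib)
  refs <- apply(lib$refs, 2, function(v)
    stats::approx(lib$grid, v, xout = grid, ties = "ordered")$y)
  if (anyNA(refs))
    stop("target grid extends beyond library support", call. = FALSE)
  reference_library(grid, refs, band_nm = lib$band_nm, peak_nm = lib$peak_nm,
                    normalize = (lib$normalization == "unit_peak"))
}
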