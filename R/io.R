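#' Read a spectral record CSV
#'
#' The record file layout mirrors the instrument export: first column
#' `wavelength_nm`, columns `I0` and `dark`, then one column per timestamped
#' transmission spectrum whose header is the acquisition time in seconds
#' (written by [write_optical_record()] as `t<seconds>`).
#'
#' @param path CSV path.
#' @param sample_period_s seconds per spectrum (default 1).
#' @return a [raw_optical_record()].
#' @export
read_optical_record <- function(path, sample_period_s = 1) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "I0", "dark")
  if (!all(need %in% names(df)))
    stop("record file must contain wavelength_nm, I0 and dark columns",
         call. = FALSE)
  tcols <- setdiff(names(df), need)
  times <- as.numeric(sub("^t", "", tcols))
  if (anyNA(times))
    stop("transmission column headers must be times in seconds (t<sec>)",
         call. = FALSE)
  ord <- order(times)
  raw_optical_record(df$wavelength_nm, df$I0, df$dark,
                     as.matrix(df[, tcols[ord], drop = FALSE]),
                     times_s = times[ord], sample_period_s = sample_period_s)
}

#' Write a spectral record CSV
#'
#' @param record a [raw_optical_record()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_optical_record <- function(record, path) {
  stopifnot(inherits(record, "mitopsi_record"))
  df <- data.frame(wavelength_nm = record$wavelengths_nm,
                   I0 = record$incident, dark = record$dark,
                   check.names = FALSE)
  tr <- as.data.frame(record$transmissions)
  names(tr) <- paste0("t", format(record$times_s, trim = TRUE, scientific = FALSE))
  utils::write.csv(cbind(df, tr), path, row.names = FALSE)
  invisible(path)
}

#' Read a reference library (CSV + metadata sidecar)
#'
#' @param path CSV with `wavelength_nm` plus one column per chromophore.
#' @param meta_path YAML sidecar recording the normalization convention, fit
#'   band and nominal peak wavelengths; defaults to `<path>.meta.yml`.
#' @return a [reference_library()].
#' @export
read_reference_library <- function(path, meta_path = paste0(path, ".meta.yml")) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop("library file must contain a wavelength_nm column", call. = FALSE)
  meta <- yaml::read_yaml(meta_path)
  refs <- as.matrix(df[, setdiff(names(df), "wavelength_nm"), drop = FALSE])
  reference_library(df$wavelength_nm, refs,
                    band_nm = as.numeric(meta$band_nm),
                    peak_nm = unlist(meta$peak_nm),
                    normalize = identical(meta$normalization, "unit_peak"))
}

#' Write a reference library (CSV + metadata sidecar)
#'
#' @param lib a [reference_library()].
#' @param path output CSV path.
#' @param meta_path YAML sidecar path, default `<path>.meta.yml`.
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(lib, path,
                                    meta_path = paste0(path, ".meta.yml")) {
  stopifnot(inherits(lib, "mitopsi_library"))
  utils::write.csv(data.frame(wavelength_nm = lib$grid, lib$refs,
                              check.names = FALSE),
                   path, row.names = FALSE)
  yaml::write_yaml(list(normalization = lib$normalization,
                        band_nm = lib$band_nm,
                        peak_nm = as.list(lib$peak_nm)), meta_path)
  invisible(path)
}

#' Read an electrode trace CSV plus config block
#'
#' The trace CSV holds `time_s, voltage_mV`; the YAML config records the
#' addition events, bath volume, protein load and total probe concentration.
#'
#' @param path trace CSV path.
#' @param config_path YAML config path, default `<path>.config.yml`.
#' @return an [electrode_trace()].
#' @export
read_electrode_trace <- function(path, config_path = paste0(path, ".config.yml")) {
  df <- utils::read.csv(path)
  cfg <- yaml::read_yaml(config_path)
  electrode_trace(df$time_s, df$voltage_mV,
                  additions = data.frame(
                    time_s = vapply(cfg$additions, `[[`, numeric(1), "time_s"),
                    amount_nmol = vapply(cfg$additions, `[[`, numeric(1),
                                         "amount_nmol")),
                  bath_volume_ml = cfg$bath_volume_ml,
                  protein_mg = cfg$protein_mg,
                  total_probe_uM = cfg$total_probe_uM)
}

#' Write an electrode trace CSV plus config block
#'
#' @param trace an [electrode_trace()].
#' @param path output trace CSV path.
#' @param config_path YAML config path, default `<path>.config.yml`.
#' @return `path`, invisibly.
#' @export
write_electrode_trace <- function(trace, path,
                                  config_path = paste0(path, ".config.yml")) {
  stopifnot(inherits(trace, "mitopsi_electrode_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s,
                              voltage_mV = trace$voltage_mV),
                   path, row.names = FALSE)
  yaml::write_yaml(list(
    additions = lapply(seq_len(nrow(trace$additions)), function(i)
      as.list(trace$additions[i, ])),
    bath_volume_ml = trace$bath_volume_ml,
    protein_mg = trace$protein_mg,
    total_probe_uM = trace$total_probe_uM), config_path)
  invisible(path)
}

#' Serialize a fitted calibration curve to a structured text file
#'
#' @param curve a [fit_calibration()] result.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_calibration_curve <- function(curve, path) {
  stopifnot(inherits(curve, "mitopsi_curve"))
  yaml::write_yaml(list(
    parameters = as.list(curve$parameters),
    covariance = lapply(seq_len(nrow(curve$covariance)),
                        function(i) as.numeric(curve$covariance[i, ])),
    domain_mV = curve$domain_mV,
    fbl_ceiling = curve$fbl_ceiling,
    normalization = curve$normalization), path)
  invisible(path)
}

#' Read a serialized calibration curve
#'
#' @param path YAML path written by [write_calibration_curve()].
#' @return a calibration curve object.
#' @export
read_calibration_curve <- function(path) {
  x <- yaml::read_yaml(path)
  p <- unlist(x$parameters)
  new_calibration_curve(p["bottom"], p["top"], p["v50_mV"], p["hill"],
                        covariance = do.call(rbind, lapply(x$covariance, as.numeric)),
                        domain_mV = as.numeric(x$domain_mV),
                        normalization = x$normalization)
}
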