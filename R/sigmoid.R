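#' Four-parameter logistic linking membrane potential to fb_L
#'
#' The calibration curve is the Prism-style "sigmoidal dose-response,
#' variable slope" logistic, decade-base, in untransformed millivolts:
#'
#'   fbl(psi) = bottom + (top - bottom) / (1 + 10^((v50 - psi) * hill))
#'
#' with `bottom`/`top` the fb_L asymptotes, `v50_mV` the half-effect
#' potential and `hill` the slope factor per mV (base-10 vs base-e is
#' absorbed into `hill`). Strictly increasing for `hill > 0`.
#'
#' @name fourpl
#' @keywords internal
NULL

fourpl <- function(psi, bottom, top, v50, hill) {
  bottom + (top - bottom) / (1 + 10^((v50 - psi) * hill))
}

# internal constructor shared by fit_calibration and read_calibration_curve
new_calibration_curve <- function(bottom, top, v50, hill, covariance = NULL,
                                  domain_mV, normalization = "unit_peak",
                                  fit_info = NULL) {
  bottom <- unname(bottom); top <- unname(top)
  v50 <- unname(v50); hill <- unname(hill)
  if (top < bottom) {  # same curve under (bottom,top,hill) -> (top,bottom,-hill)
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  if (!(top > bottom))
    stop("degenerate calibration curve: bottom equals top", call. = FALSE)
  curve <- structure(
    list(parameters = c(bottom = bottom, top = top, v50_mV = v50, hill = hill),
         covariance = covariance, domain_mV = as.numeric(domain_mV),
         fbl_ceiling = NA_real_, normalization = normalization,
         fit_info = fit_info),
    class = "mitopsi_curve")
  curve$fbl_ceiling <- evaluate_curve(curve, max(curve$domain_mV))
  curve
}

#' @export
print.mitopsi_curve <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<4PL calibration: bottom %.4f, top %.4f, v50 %.2f mV, hill %.4f /mV;\n  domain [%.1f, %.1f] mV, fbl ceiling %.4f, library normalization '%s'>\n",
              p["bottom"], p["top"], p["v50_mV"], p["hill"],
              x$domain_mV[1], x$domain_mV[2], x$fbl_ceiling, x$normalization))
  invisible(x)
}

#' Fit the variable-slope four-parameter sigmoid calibration
#'
#' Least-squares fit of the decade-base 4PL (see [fourpl]) through
#' calibration points (delta-psi in mV, fb_L). Initialization is a fixed
#' multi-start grid -- bottom/top from the data quantiles, v50 from the
#' median potential, hill over `hill_starts` in fixed order -- so the fit is
#' deterministic. The parameter covariance comes from the final Jacobian.
#'
#' @param points `data.frame` with `delta_psi_mV` and `fbl` (optionally
#'   `label`, `weight`); at least 6 points spanning both limbs.
#' @param hill_starts starting slope factors (per mV), default
#'   `c(0.01, 0.03, 0.1)`.
#' @param normalization library normalization stamp carried by the curve so
#'   calibration and application can be checked for consistency.
#' @return object of class `mitopsi_curve`: `parameters`
#'   (bottom, top, v50_mV, hill), `covariance` (4x4), `domain_mV` (range of
#'   calibrated potentials), `fbl_ceiling` (fitted fb_L at the domain top).
#' @export
fit_calibration <- function(points, hill_starts = c(0.01, 0.03, 0.1),
                            normalization = "unit_peak") {
  points <- as.data.frame(points)
  if (!all(c("delta_psi_mV", "fbl") %in% names(points)))
    stop("points needs delta_psi_mV and fbl columns", call. = FALSE)
  if (nrow(points) < 6)
    stop("need at least 6 calibration points", call. = FALSE)
  if (any(points$fbl < 0 | points$fbl > 1))
    stop("fbl values must lie in [0, 1]", call. = FALSE)
  if (stats::sd(points$fbl) < 1e-10)
    stop("degenerate calibration input: fbl is constant (bottom = top)",
         call. = FALSE)
  psi <- points$delta_psi_mV; fbl <- points$fbl
  med <- stats::median(psi)
  if (!any(psi < med) || !any(psi > med))
    stop("calibration points must span both limbs of the sigmoid",
         call. = FALSE)
  w <- if ("weight" %in% names(points)) points$weight else rep(1, nrow(points))
  b0 <- stats::quantile(fbl, 0.05, names = FALSE)
  t0 <- stats::quantile(fbl, 0.95, names = FALSE)
  attempts <- list()
  best <- NULL
  for (h0 in hill_starts) {
    res <- tryCatch({
      fit <- minpack.lm::nlsLM(
        fbl ~ fourpl(psi, bottom, top, v50, hill),
        data = data.frame(psi = psi, fbl = fbl),
        start = list(bottom = b0, top = t0, v50 = med, hill = h0),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200))
      list(fit = fit, ssr = sum(stats::residuals(fit)^2), error = NULL)
    }, error = function(e) list(fit = NULL, ssr = Inf,
                                error = conditionMessage(e)))
    attempts[[as.character(h0)]] <- res
    if (!is.null(res$fit) && (is.null(best) || res$ssr < best$ssr)) best <- res
  }
  if (is.null(best)) {
    diag <- paste(sprintf("hill start %s: %s", names(attempts),
                          vapply(attempts, function(a)
                            a$error %||% "converged", "")),
                  collapse = "; ")
    stop("4PL fit failed to converge from every start (", diag, ")",
         call. = FALSE)
  }
  co <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit),
                 error = function(e) matrix(NA_real_, 4, 4))
  new_calibration_curve(co["bottom"], co["top"], co["v50"], co["hill"],
                        covariance = vc, domain_mV = range(psi),
                        normalization = normalization,
                        fit_info = list(ssr = best$ssr,
                                        n = nrow(points),
                                        starts_tried = length(attempts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the calibration curve
#'
#' Closed-form 4PL evaluation; defined on all of R, strictly increasing for
#' positive hill, with asymptotes `bottom` and `top`.
#'
#' @param curve a `mitopsi_curve`.
#' @param delta_psi membrane potential(s), mV.
#' @return fb_L value(s).
#' @export
evaluate_curve <- function(curve, delta_psi) {
  stopifnot(inherits(curve, "mitopsi_curve"))
  p <- curve$parameters
  fourpl(delta_psi, p["bottom"], p["top"], p["v50_mV"], p["hill"])
}

#' Censored inverse prediction: fb_L to membrane potential
#'
#' For fb_L safely inside the asymptotes (more than `margin` of the span
#' from either) and an implied potential inside the calibrated domain, the
#' closed-form inverse
#'
#'   psi = v50 - log10((top - bottom)/(fbl - bottom) - 1) / hill
#'
#' is returned uncensored. Values beyond either guard -- where the sigmoid
#' is too flat for reliable inversion, as happens above the highest
#' calibrated potential -- are pinned to the corresponding domain bound and
#' reported as censored: `"above"` means the true potential probably exceeds
#' the reported value (a lower bound), `"below"` the reverse.
#'
#' @param curve a `mitopsi_curve`.
#' @param fbl fb_L value(s) in `[0, 1]`.
#' @param margin asymptote guard as a fraction of (top - bottom), default 0.01.
#' @return `data.frame`: `fbl`, `delta_psi_mV`, `censored`
#'   (`"none"`, `"above"`, `"below"`).
#' @export
invert_curve <- function(curve, fbl, margin = 0.01) {
  stopifnot(inherits(curve, "mitopsi_curve"))
  if (any(fbl < 0 | fbl > 1, na.rm = TRUE))
    stop("fbl must lie in [0, 1]", call. = FALSE)
  p <- curve$parameters
  span <- p["top"] - p["bottom"]
  lo_guard <- p["bottom"] + margin * span
  hi_guard <- p["top"] - margin * span
  psi <- rep(NA_real_, length(fbl))
  censored <- rep(NA_character_, length(fbl))
  interior <- !is.na(fbl) & fbl > lo_guard & fbl < hi_guard
  psi[interior] <- p["v50_mV"] -
    log10(span / (fbl[interior] - p["bottom"]) - 1) / p["hill"]
  censored[interior] <- "none"
  above_dom <- interior & psi > curve$domain_mV[2]
  below_dom <- interior & psi < curve$domain_mV[1]
  hi <- (!is.na(fbl) & fbl >= hi_guard) | above_dom
  lo <- (!is.na(fbl) & fbl <= lo_guard) | below_dom
  psi[hi] <- curve$domain_mV[2]; censored[hi] <- "above"
  psi[lo] <- curve$domain_mV[1]; censored[lo] <- "below"
  data.frame(fbl = fbl, delta_psi_mV = psi, censored = censored)
}

#' Pointwise bootstrap confidence band for the calibration curve
#'
#' Case-resampling bootstrap: calibration points are resampled with
#' replacement, the 4PL is refit (started from the original estimate), and
#' pointwise percentile quantiles of the refitted curves are taken on a
#' potential grid. Reproducible under a fixed seed.
#'
#' @param curve the fitted `mitopsi_curve`.
#' @param points the calibration points used for the fit.
#' @param grid potentials (mV) at which to evaluate the band.
#' @param level confidence level, default 0.95.
#' @param B bootstrap replicates, default 500 (>= 200).
#' @param seed RNG seed.
#' @return `data.frame`: `delta_psi_mV`, `fit`, `lower`, `upper`, plus
#'   attribute `failed_refits`.
#' @export
confidence_band <- function(curve, points, grid, level = 0.95, B = 500,
                            seed = 1) {
  stopifnot(inherits(curve, "mitopsi_curve"))
  if (B < 200) stop("B must be >= 200", call. = FALSE)
  points <- as.data.frame(points)
  p <- curve$parameters
  set.seed(seed)
  n <- nrow(points)
  sims <- matrix(NA_real_, length(grid), B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    pts <- points[idx, ]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fbl ~ fourpl(psi, bottom, top, v50, hill),
        data = data.frame(psi = pts$delta_psi_mV, fbl = pts$fbl),
        start = list(bottom = p[["bottom"]], top = p[["top"]],
                     v50 = p[["v50_mV"]], hill = p[["hill"]]),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) { failed <- failed + 1L; next }
    co <- stats::coef(fit)
    sims[, b] <- fourpl(grid, co["bottom"], co["top"], co["v50"], co["hill"])
  }
  if (failed > 0.1 * B)
    stop(sprintf("confidence band unavailable: %d/%d bootstrap refits failed",
                 failed, B), call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- apply(sims, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  out <- data.frame(delta_psi_mV = grid,
                    fit = as.numeric(evaluate_curve(curve, grid)),
                    lower = qs[1, ], upper = qs[2, ])
  attr(out, "failed_refits") <- failed
  out
}
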