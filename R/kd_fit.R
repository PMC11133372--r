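#' Fit a one-site saturation-binding curve
#'
#' Least-squares fit of `MFI(c) = baseline + fmax * c / (KD + c)` to a
#' concentration titration (Levenberg-Marquardt via \pkg{minpack.lm}). A
#' flat response (amplitude not distinguishable from zero) is reported as
#' non-converged, signalling an antigen non-binder, rather than as an error.
#'
#' @param concentrations Ligand concentrations in nM (>= 4 distinct positive
#'   values).
#' @param mfi Mean fluorescence intensities, one per concentration.
#' @return List with `kd` (nM), `fmax`, `baseline`, `converged` (logical).
#' @examples
#' conc <- c(0.5, 1, 5, 10, 25, 50, 100, 200, 400, 800, 1600)
#' fit_kd(conc, 10 + 500 * conc / (10 + conc))$kd
#' @export
fit_kd <- function(concentrations, mfi) {
  if (length(concentrations) != length(mfi)) {
    stop("`concentrations` and `mfi` must have the same length", call. = FALSE)
  }
  if (length(concentrations) < 4L) {
    stop("at least 4 concentration points are required", call. = FALSE)
  }
  if (any(concentrations <= 0) || anyDuplicated(concentrations)) {
    stop("concentrations must be positive and distinct", call. = FALSE)
  }
  flat <- list(kd = NA_real_, fmax = 0, baseline = mean(mfi), converged = FALSE)
  span <- diff(range(mfi))
  if (span <= 1e-9 * max(abs(mfi), 1)) return(flat)

  ord <- order(concentrations)
  conc <- concentrations[ord]
  y <- mfi[ord]
  b0 <- min(y)
  f0 <- max(y) - b0
  half <- b0 + f0 / 2
  k0 <- conc[which.min(abs(y - half))]

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline + fmax * conc / (kd + conc),
      start = list(baseline = b0, fmax = f0, kd = max(k0, min(conc))),
      lower = c(baseline = -Inf, fmax = 0, kd = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(flat)
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  distinguishable <- is.finite(se[["fmax"]]) && est[["fmax"]] > 2 * se[["fmax"]]
  list(
    kd = unname(est[["kd"]]),
    fmax = unname(est[["fmax"]]),
    baseline = unname(est[["baseline"]]),
    converged = isTRUE(distinguishable)
  )
}
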