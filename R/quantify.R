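#' Ratiometric signal from an emission spectrum
#'
#' The sensor readout is the ratio of the acceptor emission intensity
#' (around 521 nm) to the donor emission intensity (around 441 nm).  Each
#' intensity is the mean over an 11 nm window (band integral divided by
#' window width) rather than a single-pixel value, for robustness to grid
#' alignment.
#'
#' @param x Emission `spectrum`.
#' @param num_window Numerator (acceptor) window, default 516-526 nm.
#' @param den_window Denominator (donor) window, default 436-446 nm.
#' @return List of class `ratiometric_signal`: `i_num`, `i_den`, `ratio`.
#' @export
ratiometric_signal <- function(x, num_window = c(516, 526),
                               den_window = c(436, 446)) {
  stopifnot(is_spectrum(x))
  wmean <- function(w) {
    w <- as_window(w)
    integrate_spectrum(x, w) / (w$hi - w$lo)
  }
  i_num <- wmean(num_window)
  i_den <- wmean(den_window)
  if (i_den <= 0) stop_invariant("denominator window intensity is not positive")
  structure(list(i_num = i_num, i_den = i_den, ratio = i_num / i_den),
            class = "ratiometric_signal")
}

#' Ratiometric calibration with 3-sigma detection limit
#'
#' Ordinary least squares of ratio against concentration; the detection
#' limit is DL = 3 sd(blanks) / |slope| with the sample (n-1) standard
#' deviation of the blank replicates.  The linear range is reported
#' descriptively as the fitted concentration span.
#'
#' @param conc_um Concentrations in micromolar (>= 3 distinct values).
#' @param ratio Ratiometric signals, same length.
#' @param blanks Blank-replicate signals (>= 2 values).
#' @return List of class `calibration_result`: `slope`, `intercept`,
#'   `r_squared`, `linear_range`, `detection_limit`, `n_blanks`,
#'   `sigma_blank`.
#' @export
calibrate <- function(conc_um, ratio, blanks) {
  conc_um <- as.numeric(conc_um); ratio <- as.numeric(ratio)
  blanks <- as.numeric(blanks)
  stopifnot(length(conc_um) == length(ratio))
  if (length(unique(conc_um)) < 3L) {
    stop_invariant("need at least 3 distinct concentrations")
  }
  if (length(blanks) < 2L) stop_invariant("need at least 2 blank replicates")
  fit <- stats::lm(ratio ~ conc_um)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope == 0) {
    stop_invariant("calibration slope is zero; no sensitivity")
  }
  sigma_blank <- stats::sd(blanks)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r_squared_of(fit),
                 linear_range = range(conc_um),
                 detection_limit = 3 * sigma_blank / abs(slope),
                 n_blanks = length(blanks),
                 sigma_blank = sigma_blank),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Calibration: ratio = %.5g + %.5g * c, R^2 = %.5f\n  range %g-%g uM, DL = %.4g uM (3 sigma / S, n_blanks = %d)\n",
    x$intercept, x$slope, x$r_squared, x$linear_range[1], x$linear_range[2],
    x$detection_limit, x$n_blanks))
  invisible(x)
}

#' Inverse prediction from a ratiometric calibration
#'
#' @param ratio Measured ratiometric signal.
#' @param calibration A `calibration_result`.
#' @return List: `conc_um` = (ratio - intercept)/slope, `below_dl`
#'   (TRUE if the estimate is under the detection limit), `in_range`
#'   (TRUE if inside the calibrated span).
#' @export
quantify_sample <- function(ratio, calibration) {
  stopifnot(inherits(calibration, "calibration_result"),
            is_scalar_number(ratio))
  conc <- (ratio - calibration$intercept) / calibration$slope
  list(conc_um = conc,
       below_dl = conc < calibration$detection_limit,
       in_range = conc >= calibration$linear_range[1] &&
         conc <= calibration$linear_range[2])
}

#' Standard-addition quantification
#'
#' Least-squares line of ratio against added concentration; the analyte
#' concentration is the magnitude of the x-intercept, intercept/slope.
#' Each spiked level also yields a found amount
#' `(ratio_i - intercept)/slope`, giving a recovery
#' `100 * found / added` per level, and an independent base-concentration
#' estimate `ratio_i/slope - added_i` whose relative spread is reported as
#' the RSD.
#'
#' @param additions Added concentrations in uM, strictly increasing,
#'   starting at 0, >= 3 levels.
#' @param ratio Ratiometric signals, same length.
#' @return List of class `standard_addition_result`: `estimated_conc`
#'   (uM), `recoveries` (percent, one per nonzero addition), `rsd`
#'   (percent), `slope`, `intercept`, `r_squared`.
#' @export
standard_addition <- function(additions, ratio) {
  additions <- as.numeric(additions); ratio <- as.numeric(ratio)
  stopifnot(length(additions) == length(ratio))
  if (length(additions) < 3L) stop_invariant("need at least 3 addition levels")
  if (additions[1] != 0) stop_invariant("additions must start at 0 (the unspiked sample)")
  if (any(diff(additions) <= 0)) stop_invariant("additions must be strictly increasing")
  fit <- stats::lm(ratio ~ additions)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop_invariant("standard-addition slope is not positive; no sensitivity to the analyte")
  }
  est <- abs(intercept / slope)
  spiked <- additions > 0
  found <- (ratio[spiked] - intercept) / slope
  recoveries <- 100 * found / additions[spiked]
  base_est <- ratio / slope - additions
  rsd <- 100 * stats::sd(base_est) / mean(base_est)
  structure(list(estimated_conc = est, recoveries = recoveries, rsd = rsd,
                 slope = slope, intercept = intercept,
                 r_squared = r_squared_of(fit)),
            class = "standard_addition_result")
}

#' @export
print.standard_addition_result <- function(x, ...) {
  cat(sprintf(
    "Standard addition: %.4g uM found (R^2 = %.5f); recoveries %.1f-%.1f%%, RSD %.2f%%\n",
    x$estimated_conc, x$r_squared, min(x$recoveries), max(x$recoveries), x$rsd))
  invisible(x)
}

#' Interference / competition score
#'
#' Percent change of the ratiometric probe signal when a potentially
#' interfering species is present.
#'
#' @param ratio_alone Probe ratio without the species, > 0.
#' @param ratio_with Probe ratio with the species, > 0.
#' @return Percent change, `100 * (with - alone) / alone`.
#' @export
interference_score <- function(ratio_alone, ratio_with) {
  stopifnot(is_scalar_number(ratio_alone), is_scalar_number(ratio_with))
  if (ratio_alone <= 0 || ratio_with <= 0) {
    stop_invariant("ratios must be positive")
  }
  100 * (ratio_with - ratio_alone) / ratio_alone
}
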