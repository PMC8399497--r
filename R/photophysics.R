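#' Relative fluorescence quantum yield
#'
#' Gradient method against a reference standard of known quantum yield
#' (e.g. quinine sulfate, QY 0.54 in dilute sulfuric acid):
#' \deqn{\phi_x = \phi_{ST}\,\frac{Grad_x}{Grad_{ST}}\,
#'       \frac{\eta_x^2}{\eta_{ST}^2}}
#' where Grad is the slope of integrated fluorescence intensity versus
#' absorbance and eta the solvent refractive index.
#'
#' @param grad_x Gradient of the sample, > 0.
#' @param grad_st Gradient of the standard, > 0.
#' @param phi_st Quantum yield of the standard, in (0, 1].
#' @param eta_x,eta_st Solvent refractive indices (default: equal).
#' @return Quantum yield of the sample (dimensionless); values above 1
#'   are returned with a warning (they indicate an experimental problem).
#' @export
relative_qy <- function(grad_x, grad_st, phi_st, eta_x = 1.333,
                        eta_st = eta_x) {
  stopifnot(is_scalar_number(grad_x), is_scalar_number(grad_st),
            is_scalar_number(phi_st), is_scalar_number(eta_x),
            is_scalar_number(eta_st))
  if (grad_st <= 0) stop_invariant("standard gradient must be positive")
  if (grad_x <= 0) stop_invariant("sample gradient must be positive")
  if (phi_st <= 0 || phi_st > 1) stop_invariant("phi_st must lie in (0, 1]")
  if (eta_x <= 0 || eta_st <= 0) stop_invariant("refractive indices must be positive")
  phi <- phi_st * (grad_x / grad_st) * (eta_x^2 / eta_st^2)
  if (phi > 1) {
    warning("computed quantum yield exceeds 1 (", signif(phi, 4),
            "); check gradients and inner-filter effects", call. = FALSE)
  }
  phi
}

#' Gradient of integrated fluorescence versus absorbance
#'
#' Least-squares slope (free intercept) of the dilution series used in the
#' relative quantum-yield method.  Absorbances above 0.1 trigger a warning
#' because inner-filter effects bend the line.
#'
#' @param absorbance Absorbance values (>= 3 points, not all equal).
#' @param integrated_intensity Integrated fluorescence per dilution.
#' @return Slope (a.u. nm per absorbance unit).
#' @export
gradient_from_series <- function(absorbance, integrated_intensity) {
  absorbance <- as.numeric(absorbance)
  integrated_intensity <- as.numeric(integrated_intensity)
  stopifnot(length(absorbance) == length(integrated_intensity))
  if (length(absorbance) < 3L) stop_invariant("need at least 3 dilution points")
  if (stats::sd(absorbance) == 0) {
    stop_invariant("absorbances are constant; the gradient is undefined")
  }
  if (any(absorbance > 0.1)) {
    warning("absorbance above 0.1: inner-filter effects may bias the gradient",
            call. = FALSE)
  }
  unname(stats::coef(stats::lm(integrated_intensity ~ absorbance))[2])
}

#' Photostability drift summary
#'
#' Summarizes a fluorescence kinetic trace under continuous illumination:
#' percent retention (last/first) and the least-squares drift slope in
#' percent of the initial intensity per hour.
#'
#' @param time_s Time points in seconds, increasing, >= 2.
#' @param intensity Fluorescence intensities, first value > 0.
#' @return List: `retention_pct`, `slope_pct_per_hour`.
#' @export
photostability_drift <- function(time_s, intensity) {
  time_s <- as.numeric(time_s); intensity <- as.numeric(intensity)
  stopifnot(length(time_s) == length(intensity), length(time_s) >= 2L)
  if (any(diff(time_s) <= 0)) stop_invariant("time points must be increasing")
  if (intensity[1] <= 0) stop_invariant("initial intensity must be positive")
  rel <- 100 * intensity / intensity[1]
  hours <- time_s / 3600
  list(retention_pct = rel[length(rel)],
       slope_pct_per_hour = unname(stats::coef(stats::lm(rel ~ hours))[2]))
}

#' Reactivity classification thresholds
#'
#' Default viability bands of the five-point cytocompatibility scale as
#' used here: none >= 90%, mild 70-90%, moderate 30-70%, severe < 30%.
#' Thresholds are the lower bounds of the none/mild/moderate classes and
#' can be overridden.
#'
#' @param none,mild,moderate Lower viability bounds (percent) of the
#'   respective classes; must be strictly decreasing.
#' @return Named numeric vector of thresholds.
#' @export
reactivity_bands <- function(none = 90, mild = 70, moderate = 30) {
  if (!(none > mild && mild > moderate && moderate > 0)) {
    stop_invariant("bands must satisfy none > mild > moderate > 0")
  }
  c(none = none, mild = mild, moderate = moderate)
}

classify_reactivity <- function(viability_pct, bands = reactivity_bands()) {
  if (viability_pct >= bands["none"]) "none"
  else if (viability_pct >= bands["mild"]) "mild"
  else if (viability_pct >= bands["moderate"]) "moderate"
  else "severe"
}

#' Cell viability from crystal-violet absorbances
#'
#' Viability is `100 * A_treated / A_control` at 595 nm, with a reactivity
#' class from the five-point scale (see [reactivity_bands()]).  Vector
#' inputs are interpreted as replicate wells and averaged per condition
#' before the ratio is taken (wells are unpaired on a 96-well plate).
#'
#' @param a_s Absorbance(s) of treated cells, >= 0.
#' @param a_c Absorbance(s) of control cells; mean must be > 0.
#' @param bands Classification thresholds from [reactivity_bands()].
#' @return List of class `viability_record`: `a_s`, `a_c` (condition
#'   means), `viability` (percent), `reactivity`.
#' @export
viability <- function(a_s, a_c, bands = reactivity_bands()) {
  a_s <- mean(as.numeric(a_s)); a_c <- mean(as.numeric(a_c))
  if (!is.finite(a_c) || a_c <= 0) stop_invariant("control absorbance must be positive")
  if (!is.finite(a_s) || a_s < 0) stop_invariant("treated absorbance must be >= 0")
  v <- 100 * a_s / a_c
  structure(list(a_s = a_s, a_c = a_c, viability = v,
                 reactivity = classify_reactivity(v, bands)),
            class = "viability_record")
}

#' @export
print.viability_record <- function(x, ...) {
  cat(sprintf("Viability %.1f%% (A_S = %.4g, A_C = %.4g): %s reactivity\n",
              x$viability, x$a_s, x$a_c, x$reactivity))
  invisible(x)
}

#' Viability from a plate-layout table
#'
#' @param plate Data frame with columns `condition`
#'   (control/treated) and `absorbance_595nm`, as produced by
#'   [simulate_viability_plate()].
#' @param bands Classification thresholds.
#' @return A `viability_record` (means over wells per condition).
#' @export
viability_from_plate <- function(plate, bands = reactivity_bands()) {
  stopifnot(is.data.frame(plate),
            all(c("condition", "absorbance_595nm") %in% names(plate)))
  viability(plate$absorbance_595nm[plate$condition == "treated"],
            plate$absorbance_595nm[plate$condition == "control"],
            bands)
}
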