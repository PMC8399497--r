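#' Quenching titration table
#'
#' Integrated donor fluorescence versus quencher (acceptor) concentration,
#' the input to the modified Stern-Volmer analysis.
#'
#' @param conc_um Quencher concentrations in micromolar, strictly
#'   increasing, > 0.
#' @param F Integrated donor fluorescence at each concentration.
#' @param F0 Integrated donor fluorescence with no quencher, > 0.
#' @return A `quench_table` object.
#' @export
quench_table <- function(conc_um, F, F0) {
  conc_um <- as.numeric(conc_um); F <- as.numeric(F)
  stopifnot(is_scalar_number(F0), length(conc_um) == length(F))
  if (F0 <= 0) stop_invariant("F0 must be positive")
  if (any(conc_um <= 0)) stop_invariant("quencher concentrations must be > 0")
  if (any(diff(conc_um) <= 0)) stop_invariant("concentrations must be strictly increasing")
  if (any(F <= 0)) stop_invariant("fluorescence values must be positive")
  if (any(F > 1.02 * F0)) {
    stop_invariant("F exceeds F0 by more than 2%; check units/baseline")
  }
  F <- pmin(F, F0)
  structure(list(conc_um = conc_um, F = F, F0 = F0), class = "quench_table")
}

#' Modified Stern-Volmer (Lehrer) binding fit
#'
#' Fits the Lehrer linearization of fluorescence quenching,
#' \deqn{\frac{F_0}{F_0 - F} = \frac{1}{f_a} + \frac{1}{f_a K [Q]},}
#' by ordinary least squares of F0/(F0-F) against 1/\[Q\] (concentrations
#' converted to molar so K comes out in M^-1).  The slope is 1/(f_a K) and
#' the intercept 1/f_a, so K = intercept/slope and the accessible fraction
#' f_a = 1/intercept.  In a FRET titration the "accessible fraction" is the
#' transfer efficiency of the bound complex.
#'
#' @param table A `quench_table`.
#' @return List of class `binding_fit`: `K` (M^-1), `f_a`, `r_squared`,
#'   `n_points`, `slope`, `intercept`.
#' @export
stern_volmer_fit <- function(table) {
  stopifnot(inherits(table, "quench_table"))
  usable <- table$F < table$F0
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with F = F0 excluded (no measurable quenching)",
            call. = FALSE)
  }
  conc_m <- table$conc_um[usable] * 1e-6
  F <- table$F[usable]
  if (length(F) < 3L) {
    stop_invariant("need at least 3 usable points (F < F0, [Q] > 0), got ", length(F))
  }
  y <- table$F0 / (table$F0 - F)
  x <- 1 / conc_m
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  K <- intercept / slope
  if (!is.finite(K) || K <= 0 || intercept <= 0) {
    stop_invariant("fitted binding constant is nonpositive; the Lehrer model does not describe these data")
  }
  structure(list(K = K, f_a = 1 / intercept,
                 r_squared = r_squared_of(fit),
                 n_points = length(F), slope = slope, intercept = intercept),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Modified Stern-Volmer fit: K = %.4g M^-1, f_a = %.4f, R^2 = %.5f (n = %d)\n",
              x$K, x$f_a, x$r_squared, x$n_points))
  invisible(x)
}
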