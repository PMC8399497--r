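#' Donor-acceptor spectral overlap integral
#'
#' Computes the overlap integral
#' \deqn{J = \frac{\int F_D(\lambda)\,\varepsilon_A(\lambda)\,\lambda^4\,d\lambda}
#'                {\int F_D(\lambda)\,d\lambda}}
#' between the donor emission \eqn{F_D} and the acceptor molar absorptivity
#' \eqn{\varepsilon_A}.  The donor emission is area-normalized over its full
#' support, so J is invariant to the arbitrary intensity units of the
#' fluorimeter.  Integration is trapezoidal on the merged wavelength grid of
#' the two spectra restricted to the intersection of their supports.
#'
#' @param donor_emission `spectrum` of kind `"emission"`.
#' @param acceptor_absorptivity `spectrum` of kind `"molar_absorptivity"`
#'   (M^-1 cm^-1).  An absorbance spectrum is rejected: without path length
#'   and concentration it cannot be converted.
#' @return A list of class `overlap_integral` with `J_nm4` (M^-1 cm^-1 nm^4)
#'   and `J_cm3` (M^-1 cm^3; conversion factor 1e-28).
#' @export
overlap_integral <- function(donor_emission, acceptor_absorptivity) {
  stopifnot(is_spectrum(donor_emission), is_spectrum(acceptor_absorptivity))
  if (donor_emission$kind != "emission") {
    stop_invariant("donor spectrum must have kind 'emission', got '",
                   donor_emission$kind, "'")
  }
  if (acceptor_absorptivity$kind != "molar_absorptivity") {
    stop_invariant("acceptor spectrum must be molar absorptivity (M^-1 cm^-1); ",
                   "absorbance cannot be used without path length and concentration")
  }
  lo <- max(min(donor_emission$wavelength), min(acceptor_absorptivity$wavelength))
  hi <- min(max(donor_emission$wavelength), max(acceptor_absorptivity$wavelength))
  if (!(lo < hi)) {
    stop_invariant("donor emission and acceptor absorptivity have disjoint supports")
  }
  donor_area <- trapz(donor_emission$wavelength, donor_emission$value)
  if (donor_area <= 0) stop_invariant("donor emission has nonpositive area")

  grid <- sort(unique(c(
    donor_emission$wavelength[donor_emission$wavelength >= lo &
                              donor_emission$wavelength <= hi],
    acceptor_absorptivity$wavelength[acceptor_absorptivity$wavelength >= lo &
                                     acceptor_absorptivity$wavelength <= hi],
    lo, hi)))
  fd <- stats::approx(donor_emission$wavelength, donor_emission$value,
                      xout = grid)$y / donor_area
  ea <- stats::approx(acceptor_absorptivity$wavelength,
                      acceptor_absorptivity$value, xout = grid)$y
  j_nm4 <- trapz(grid, fd * ea * grid^4)
  structure(list(J_nm4 = j_nm4, J_cm3 = j_nm4 * 1e-28),
            class = "overlap_integral")
}

#' @export
print.overlap_integral <- function(x, ...) {
  cat(sprintf("Overlap integral J = %.6g M^-1 cm^-1 nm^4 (= %.6g M^-1 cm^3)\n",
              x$J_nm4, x$J_cm3))
  invisible(x)
}

#' Förster distance from the overlap integral
#'
#' \eqn{R_0^6\,(\mathrm{cm}^6) = 8.79\times 10^{-25}\,\kappa^2\,\eta^{-4}\,
#' \phi\, J} with J in M^-1 cm^3, converted to nm.  The result is
#' cross-validated against the equivalent Angstrom-scale form
#' \eqn{R_0(\mathrm{\AA}) = 0.211\,[\kappa^2\eta^{-4}\phi\,
#' J(\mathrm{M^{-1}cm^{-1}nm^4})]^{1/6}}; a disagreement beyond 1% aborts,
#' since it can only come from a unit mistake in J.
#'
#' @param J Overlap integral in M^-1 cm^3, or an `overlap_integral` object.
#' @param kappa2 Dipole orientation factor, default 2/3 (isotropic dynamic
#'   averaging).
#' @param eta Refractive index of the medium, default 1.336 (aqueous buffer).
#' @param phi Donor fluorescence quantum yield in (0, 1].
#' @return Förster distance R0 in nm.
#' @export
forster_distance <- function(J, kappa2 = 2 / 3, eta = 1.336, phi) {
  if (inherits(J, "overlap_integral")) J <- J$J_cm3
  stopifnot(is_scalar_number(J), is_scalar_number(kappa2),
            is_scalar_number(eta), is_scalar_number(phi))
  if (J <= 0 || kappa2 <= 0 || eta <= 0 || phi <= 0) {
    stop_invariant("J, kappa2, eta and phi must all be positive")
  }
  if (kappa2 > 4) stop_invariant("kappa2 must lie in (0, 4]")
  if (phi > 1) stop_invariant("quantum yield phi must be <= 1")

  r0_cm6 <- 8.79e-25 * kappa2 * eta^-4 * phi * J
  r0_nm <- r0_cm6^(1 / 6) * 1e7

  r0_check_nm <- 0.211 * (kappa2 * eta^-4 * phi * (J * 1e28))^(1 / 6) / 10
  if (abs(r0_nm - r0_check_nm) / r0_check_nm > 0.01) {
    stop_invariant(sprintf(
      "unit cross-check failed: cm-form gives %.4g nm, Angstrom-form %.4g nm; J is probably in the wrong units",
      r0_nm, r0_check_nm))
  }
  r0_nm
}

#' FRET efficiency from integrated donor fluorescence
#'
#' E = 1 - F_DA / F_D, where F_DA is the donor integrated fluorescence in
#' the presence of the acceptor and F_D the donor integrated fluorescence
#' alone.  Small noise-driven excesses (F_DA up to 2% above F_D) clip to
#' E = 0 with a warning; larger excesses abort, since they indicate a unit
#' or baseline mistake rather than noise.
#'
#' @param f_da Integrated donor fluorescence with acceptor (a.u. nm).
#' @param f_d Integrated donor fluorescence alone (a.u. nm), > 0.
#' @return Efficiency in \[0, 1\].
#' @export
efficiency_from_fluorescence <- function(f_da, f_d) {
  stopifnot(is_scalar_number(f_da), is_scalar_number(f_d))
  if (f_d <= 0) stop_invariant("F_D must be positive")
  if (f_da < 0) stop_invariant("F_DA must be nonnegative")
  if (f_da > f_d) {
    if (f_da <= 1.02 * f_d) {
      warning("F_DA slightly exceeds F_D (", signif(100 * (f_da / f_d - 1), 3),
              "%); clipping efficiency to 0", call. = FALSE)
      return(0)
    }
    stop_invariant("F_DA exceeds F_D by more than 2%; check units/baseline")
  }
  1 - f_da / f_d
}

#' FRET efficiency from geometry (multi-acceptor form)
#'
#' For a nanoparticle donor engaging `n` equivalent proximal acceptors at
#' distance `r`: \eqn{E = n R_0^6 / (n R_0^6 + r^6)}.
#'
#' @param r Donor-acceptor distance in nm, > 0.
#' @param R0 Förster distance in nm, > 0.
#' @param n Number of acceptors per donor, >= 1.
#' @return Efficiency in (0, 1).
#' @export
efficiency_from_distance <- function(r, R0, n = 1) {
  stopifnot(is_scalar_number(r), is_scalar_number(R0), is_scalar_number(n))
  if (r <= 0 || R0 <= 0) stop_invariant("r and R0 must be positive")
  if (n < 1) stop_invariant("n must be >= 1")
  n * R0^6 / (n * R0^6 + r^6)
}

#' Donor-acceptor distance from efficiency
#'
#' Inverts the multi-acceptor efficiency relation:
#' \eqn{r = R_0\,[n(1-E)/E]^{1/6}}.
#'
#' @param E Efficiency, strictly inside (0, 1).
#' @param R0 Förster distance in nm.
#' @param n Number of acceptors per donor, >= 1.
#' @return Distance r in nm.
#' @export
distance_from_efficiency <- function(E, R0, n = 1) {
  stopifnot(is_scalar_number(E), is_scalar_number(R0), is_scalar_number(n))
  if (E <= 0 || E >= 1) {
    stop_invariant("E must lie strictly inside (0, 1); the inversion is degenerate at the endpoints")
  }
  if (R0 <= 0) stop_invariant("R0 must be positive")
  if (n < 1) stop_invariant("n must be >= 1")
  R0 * (n * (1 - E) / E)^(1 / 6)
}

#' Distance-regime check for FRET distance estimates
#'
#' FRET distance estimates are reliable only when the separation is
#' comparable to the Förster distance; the accepted working band is
#' 0.5 R0 < r < 1.5 R0 (strict).
#'
#' @param r Donor-acceptor distance, nm.
#' @param R0 Förster distance, nm.
#' @return List with `ok` (logical) and `ratio` (r / R0).
#' @export
check_regime <- function(r, R0) {
  stopifnot(is_scalar_number(r), is_scalar_number(R0))
  if (r <= 0 || R0 <= 0) stop_invariant("r and R0 must be positive")
  ratio <- r / R0
  list(ok = ratio > 0.5 && ratio < 1.5, ratio = ratio)
}

#' Unmix a composite spectrum against donor and acceptor references
#'
#' Nonnegative least-squares decomposition
#' `composite ~ a * donor_ref + b * acceptor_ref` on a common wavelength
#' grid (the composite grid restricted to the intersection of all three
#' supports).  With two components the NNLS solution is exact: solve the
#' unconstrained 2x2 normal equations; if a coefficient is negative, clamp
#' it to zero and refit the other by simple projection.
#'
#' @param composite,donor_ref,acceptor_ref `spectrum` objects.
#' @return List of class `unmix_result`: `donor_coeff`, `acceptor_coeff`,
#'   `residual_rms` (RMS residual as a fraction of the composite RMS).
#' @export
unmix <- function(composite, donor_ref, acceptor_ref) {
  stopifnot(is_spectrum(composite), is_spectrum(donor_ref),
            is_spectrum(acceptor_ref))
  lo <- max(min(composite$wavelength), min(donor_ref$wavelength),
            min(acceptor_ref$wavelength))
  hi <- min(max(composite$wavelength), max(donor_ref$wavelength),
            max(acceptor_ref$wavelength))
  if (!(lo < hi)) stop_invariant("spectra have no common wavelength support")
  grid <- composite$wavelength[composite$wavelength >= lo &
                               composite$wavelength <= hi]
  if (length(grid) < 3L) stop_invariant("fewer than 3 shared wavelength points")
  y <- stats::approx(composite$wavelength, composite$value, xout = grid)$y
  d <- stats::approx(donor_ref$wavelength, donor_ref$value, xout = grid)$y
  a <- stats::approx(acceptor_ref$wavelength, acceptor_ref$value, xout = grid)$y

  cos_sim <- sum(d * a) / sqrt(sum(d^2) * sum(a^2))
  if (!is.finite(cos_sim) || cos_sim > 0.999) {
    stop_invariant("donor and acceptor references are collinear (cosine similarity ",
                   signif(cos_sim, 4), " > 0.999); unmixing is ill-posed")
  }

  dd <- sum(d * d); aa <- sum(a * a); da <- sum(d * a)
  dy <- sum(d * y); ay <- sum(a * y)
  det <- dd * aa - da^2
  cd <- (aa * dy - da * ay) / det
  ca <- (dd * ay - da * dy) / det
  if (cd < 0) { cd <- 0; ca <- max(0, ay / aa) }
  if (ca < 0) { ca <- 0; cd <- max(0, dy / dd) }

  resid <- y - cd * d - ca * a
  rms <- sqrt(mean(y^2))
  structure(list(donor_coeff = cd, acceptor_coeff = ca,
                 residual_rms = if (rms > 0) sqrt(mean(resid^2)) / rms else 0),
            class = "unmix_result")
}

#' Select the donor excitation wavelength by maximal spectral overlap
#'
#' Given candidate donor emission spectra recorded at different excitation
#' wavelengths, returns the excitation whose emission has the largest
#' overlap integral with the acceptor absorptivity.  Ties break to the
#' lowest excitation wavelength.
#'
#' @param candidates Named list of emission `spectrum` objects; names are
#'   excitation wavelengths in nm.
#' @param acceptor_absorptivity `spectrum` of kind `"molar_absorptivity"`.
#' @return List with `excitation` (nm) and `J` (named vector of J_nm4 per
#'   candidate).
#' @export
select_excitation <- function(candidates, acceptor_absorptivity) {
  if (!is.list(candidates) || length(candidates) == 0L) {
    stop_invariant("need at least one candidate emission spectrum")
  }
  exc <- as.numeric(names(candidates))
  if (anyNA(exc)) stop_invariant("candidate names must be excitation wavelengths in nm")
  j <- vapply(candidates, function(s) {
    overlap_integral(s, acceptor_absorptivity)$J_nm4
  }, numeric(1))
  best <- which(j == max(j))
  pick <- best[which.min(exc[best])]
  list(excitation = exc[pick], J = stats::setNames(j, names(candidates)))
}

#' Bundle of FRET photophysical parameters
#'
#' Collects the quantities that characterize one donor-acceptor system and
#' records whether the (E, R0, r, n) subset is internally consistent with
#' the multi-acceptor efficiency relation.
#'
#' @param J `overlap_integral` object or J in M^-1 cm^3 (optional).
#' @param E Efficiency in \[0, 1\] (optional).
#' @param R0,r Distances in nm (optional).
#' @param n Acceptors per donor (optional).
#' @param kappa2,eta,phi Orientation factor, refractive index, donor
#'   quantum yield.
#' @param tol Relative tolerance for the consistency flag (default 0.01).
#' @return List of class `fret_params`; `consistent` is `NA` unless all of
#'   E, R0, r, n are supplied.
#' @export
fret_params <- function(J = NULL, E = NULL, R0 = NULL, r = NULL, n = NULL,
                        kappa2 = 2 / 3, eta = 1.336, phi = NULL, tol = 0.01) {
  if (!is.null(E) && (E < 0 || E > 1)) stop_invariant("E must lie in [0, 1]")
  if (!is.null(R0) && R0 <= 0) stop_invariant("R0 must be positive")
  if (!is.null(r) && r <= 0) stop_invariant("r must be positive")
  if (kappa2 <= 0 || kappa2 > 4) stop_invariant("kappa2 must lie in (0, 4]")
  consistent <- NA
  if (!is.null(E) && !is.null(R0) && !is.null(r) && !is.null(n)) {
    e_geom <- efficiency_from_distance(r, R0, n)
    consistent <- abs(e_geom - E) <= tol * max(E, .Machine$double.eps)
  }
  structure(list(J = J, E = E, R0 = R0, r = r, n = n,
                 kappa2 = kappa2, eta = eta, phi = phi,
                 consistent = consistent),
            class = "fret_params")
}

#' @export
print.fret_params <- function(x, ...) {
  fmt <- function(v, lab, unit = "") {
    if (!is.null(v) && !inherits(v, "overlap_integral"))
      cat(sprintf("  %-8s %.6g %s\n", lab, v, unit))
  }
  cat("FRET parameters\n")
  if (inherits(x$J, "overlap_integral")) {
    cat(sprintf("  %-8s %.6g M^-1 cm^-1 nm^4\n", "J", x$J$J_nm4))
  } else fmt(x$J, "J", "M^-1 cm^3")
  fmt(x$E, "E"); fmt(x$R0, "R0", "nm"); fmt(x$r, "r", "nm"); fmt(x$n, "n")
  fmt(x$kappa2, "kappa2"); fmt(x$eta, "eta"); fmt(x$phi, "phi")
  if (!is.na(x$consistent)) {
    cat("  (E, R0, r, n) geometry-consistent:", x$consistent, "\n")
  }
  invisible(x)
}

#' Analyze a FRET titration series
#'
#' Full pipeline from a titration of donor with increasing acceptor
#' concentration: each composite spectrum is unmixed against the donor-only
#' and acceptor-emission references, the donor coefficient gives the donor
#' integrated fluorescence F_DA at that acceptor concentration, and the
#' resulting quench table is fitted with the modified Stern-Volmer (Lehrer)
#' model.  Because quenching at concentration c is the product of the bound
#' fraction and the per-complex transfer efficiency E, the Lehrer accessible
#' fraction estimates E and the fitted association constant estimates the
#' binding constant K.
#'
#' @param titration A `titration_series` (see [simulate_titration()]) or a
#'   list with elements `conc_um`, `spectra`, `donor_ref`, `acceptor_ref`.
#' @param donor_window Window (nm) over which donor fluorescence is
#'   integrated; default `c(390, 500)` brackets the 441/456 nm donor band.
#' @return List of class `titration_fit`: `E` (efficiency estimate),
#'   `K_Minv`, `r_squared`, `apparent_E` (theta*E per point), `quench`
#'   (the quench table), `unmix_residuals`.
#' @export
analyze_titration <- function(titration, donor_window = c(390, 500)) {
  stopifnot(is.list(titration),
            !is.null(titration$conc_um), !is.null(titration$spectra))
  conc <- titration$conc_um
  f_d <- integrate_spectrum(titration$donor_ref, donor_window)
  coeffs <- numeric(length(conc))
  resids <- numeric(length(conc))
  for (i in seq_along(conc)) {
    u <- unmix(titration$spectra[[i]], titration$donor_ref,
               titration$acceptor_ref)
    coeffs[i] <- u$donor_coeff
    resids[i] <- u$residual_rms
  }
  use <- conc > 0
  qt <- quench_table(conc_um = conc[use], F = coeffs[use] * f_d, F0 = f_d)
  fit <- stern_volmer_fit(qt)
  apparent <- 1 - coeffs[use]
  structure(list(E = fit$f_a, K_Minv = fit$K, r_squared = fit$r_squared,
                 apparent_E = stats::setNames(apparent, conc[use]),
                 quench = qt, unmix_residuals = resids),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit: E = %.4f, K = %.4g M^-1, R^2 = %.5f (%d points)\n",
              x$E, x$K_Minv, x$r_squared, length(x$apparent_E)))
  invisible(x)
}
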