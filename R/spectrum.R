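#' Spectrum objects
#'
#' A `spectrum` is the numeric substrate of the package: a signal sampled on
#' a strictly increasing wavelength grid.  The `kind` records what the
#' values mean and gates which operations are allowed downstream (e.g. the
#' overlap integral requires an emission spectrum and a molar-absorptivity
#' spectrum).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param value Numeric vector of signal values: fluorescence intensity
#'   (arbitrary units), absorbance (dimensionless), or molar absorptivity
#'   (M^-1 cm^-1) depending on `kind`.
#' @param kind One of `"emission"`, `"absorbance"`, `"molar_absorptivity"`.
#' @param meta Named list of free-form provenance (source path, excitation
#'   wavelength, concentrations, ...).
#' @return An object of class `spectrum`: a list with elements
#'   `wavelength`, `value`, `kind`, `meta`.
#' @examples
#' s <- spectrum(400:500, dnorm(400:500, 450, 10), "emission")
#' peak_wavelength(s)
#' @export
spectrum <- function(wavelength, value,
                     kind = c("emission", "absorbance", "molar_absorptivity"),
                     meta = list()) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) < 2L) {
    stop_invariant("a spectrum needs at least 2 points, got ", length(wavelength))
  }
  if (length(wavelength) != length(value)) {
    stop_invariant("wavelength and value lengths differ (",
                   length(wavelength), " vs ", length(value), ")")
  }
  if (anyNA(wavelength) || any(!is.finite(wavelength))) {
    stop_invariant("wavelengths must be finite")
  }
  if (any(diff(wavelength) <= 0)) {
    stop_invariant("wavelengths must be strictly increasing")
  }
  if (anyNA(value) || any(!is.finite(value))) {
    stop_invariant("spectrum values must be finite")
  }
  if (kind == "molar_absorptivity" && any(value < 0)) {
    stop_invariant("molar absorptivity values must be >= 0")
  }
  structure(
    list(wavelength = wavelength, value = value, kind = kind, meta = meta),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %.4g-%.4g nm, peak %.4g at %.4g nm>\n",
              x$kind, length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              max(x$value), peak_wavelength(x)))
  invisible(x)
}

#' @rdname spectrum
#' @param x A `spectrum`.
#' @export
is_spectrum <- function(x) inherits(x, "spectrum")

#' Wavelength of maximum signal
#' @param x A `spectrum`.
#' @return Wavelength (nm) at which `value` is maximal (first on ties).
#' @export
peak_wavelength <- function(x) {
  stopifnot(is_spectrum(x))
  x$wavelength[which.max(x$value)]
}

#' Wavelength window
#'
#' Integration / band bounds in nm, restricted to the instrument range
#' 200-800 nm.
#'
#' @param lo,hi Window bounds in nm, `lo < hi`.
#' @return A `wavelength_window` object.
#' @export
wavelength_window <- function(lo, hi) {
  stopifnot(is_scalar_number(lo), is_scalar_number(hi))
  if (!(lo < hi)) stop_invariant("window requires lo < hi, got [", lo, ", ", hi, "]")
  if (lo < 200 || hi > 800) {
    stop_invariant("window [", lo, ", ", hi, "] outside instrument range 200-800 nm")
  }
  structure(list(lo = lo, hi = hi), class = "wavelength_window")
}

as_window <- function(w) {
  if (inherits(w, "wavelength_window")) return(w)
  if (is.numeric(w) && length(w) == 2L) return(wavelength_window(w[1], w[2]))
  stop_invariant("cannot interpret window; give wavelength_window() or c(lo, hi)")
}

#' Read a spectrum from a delimited text file
#'
#' Reads two-column wavelength/value files as exported by common
#' spectrometer software.  Comma and tab delimiters are auto-detected,
#' `#`-prefixed lines and a single non-numeric header line are skipped,
#' rows are sorted by wavelength, and duplicated wavelengths are collapsed
#' to their arithmetic mean.
#'
#' @param path Path to a CSV/TSV file: column 1 wavelength (nm), column 2
#'   value.
#' @inheritParams spectrum
#' @return A `spectrum`; `meta$source` records `path`.
#' @export
read_spectrum <- function(path,
                          kind = c("emission", "absorbance", "molar_absorptivity")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop_invariant("no data rows in ", path)

  sep <- if (grepl("\t", lines[idx[1]])) "\t" else if (grepl(",", lines[idx[1]])) "," else ""
  parse_row <- function(line) {
    fields <- if (sep == "") strsplit(trimws(line), "\\s+")[[1]] else
      trimws(strsplit(line, sep, fixed = TRUE)[[1]])
    suppressWarnings(as.numeric(fields))
  }

  first <- parse_row(lines[idx[1]])
  header_skipped <- FALSE
  if (length(first) >= 2L && anyNA(first[1:2])) {
    # single header line allowed
    idx <- idx[-1]
    header_skipped <- TRUE
    if (length(idx) == 0L) stop_invariant("no numeric rows in ", path)
  }

  wl <- numeric(length(idx))
  val <- numeric(length(idx))
  for (i in seq_along(idx)) {
    row <- parse_row(lines[idx[i]])
    if (length(row) < 2L || anyNA(row[1:2])) {
      stop_invariant("non-numeric data at line ", idx[i], " of ", path,
                     ": '", lines[idx[i]], "'")
    }
    wl[i] <- row[1]
    val[i] <- row[2]
  }
  if (length(wl) < 2L) stop_invariant("fewer than 2 data rows in ", path)

  ord <- order(wl)
  wl <- wl[ord]; val <- val[ord]
  if (anyDuplicated(wl)) {
    val <- as.numeric(tapply(val, factor(wl, levels = unique(wl)), mean))
    wl <- unique(wl)
  }
  spectrum(wl, val, kind,
           meta = list(source = path, header_skipped = header_skipped))
}

#' Write a spectrum to a CSV file
#'
#' Values are written with 17 significant digits so that
#' `read_spectrum(write_spectrum(s))` round-trips the numeric payload at
#' full double precision.
#'
#' @param x A `spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(is_spectrum(x))
  lines <- c("wavelength_nm,value",
             sprintf("%.17g,%.17g", x$wavelength, x$value))
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; never extrapolates.
#'
#' @param x A `spectrum`.
#' @param grid Strictly increasing wavelength vector, fully inside the
#'   support of `x`.
#' @return A `spectrum` of the same `kind` on `grid`.
#' @export
resample_spectrum <- function(x, grid) {
  stopifnot(is_spectrum(x))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop_invariant("resampling grid must be strictly increasing")
  lo <- min(x$wavelength); hi <- max(x$wavelength)
  if (grid[1] < lo || grid[length(grid)] > hi) {
    stop_invariant(sprintf(
      "grid [%.6g, %.6g] extends outside spectrum support [%.6g, %.6g]; refusing to extrapolate",
      grid[1], grid[length(grid)], lo, hi))
  }
  v <- stats::approx(x$wavelength, x$value, xout = grid, method = "linear")$y
  spectrum(grid, v, x$kind, meta = x$meta)
}

#' Integrate a spectrum over a wavelength window
#'
#' Trapezoidal integral; window endpoints inside the support are included
#' by linear interpolation, and windows extending past the support are
#' clipped to it.
#'
#' @param x A `spectrum`.
#' @param window `NULL` (full support), a `wavelength_window`, or `c(lo, hi)`.
#' @return Scalar integral in value-units x nm.
#' @export
integrate_spectrum <- function(x, window = NULL) {
  stopifnot(is_spectrum(x))
  if (is.null(window)) return(trapz(x$wavelength, x$value))
  w <- as_window(window)
  lo <- max(w$lo, min(x$wavelength))
  hi <- min(w$hi, max(x$wavelength))
  if (!(lo < hi)) {
    stop_invariant(sprintf("window [%g, %g] does not overlap spectrum support [%g, %g]",
                           w$lo, w$hi, min(x$wavelength), max(x$wavelength)))
  }
  inside <- x$wavelength > lo & x$wavelength < hi
  grid <- unique(sort(c(lo, x$wavelength[inside], hi)))
  v <- stats::approx(x$wavelength, x$value, xout = grid, method = "linear")$y
  trapz(grid, v)
}

#' Normalize a spectrum
#'
#' @param x A `spectrum`.
#' @param mode `"peak"` scales the maximum value to 1; `"area"` scales the
#'   trapezoidal area over the full support to 1.
#' @return The normalized `spectrum`.
#' @export
normalize_spectrum <- function(x, mode = c("peak", "area")) {
  stopifnot(is_spectrum(x))
  mode <- match.arg(mode)
  denom <- if (mode == "peak") max(x$value) else trapz(x$wavelength, x$value)
  if (!is.finite(denom) || denom == 0) {
    stop_invariant("cannot ", mode, "-normalize: ", mode, " is zero")
  }
  spectrum(x$wavelength, x$value / denom, x$kind, meta = x$meta)
}
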