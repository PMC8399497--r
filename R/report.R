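#' Run manifest for reproducible reports
#'
#' Every machine-readable report emitted by the package embeds a manifest:
#' the analysis name, a snapshot of the configuration that produced it,
#' the RNG seed (if any), input/output paths and the package version.
#' Replaying a manifest with the same package version reproduces seeded
#' outputs exactly.
#'
#' @param command Name of the analysis (e.g. "titration-analyze").
#' @param config Named list snapshot of parameters.
#' @param seed Integer seed or `NULL`.
#' @param inputs,outputs Character vectors of file paths.
#' @return A `run_manifest` object.
#' @export
run_manifest <- function(command, config = list(), seed = NULL,
                         inputs = character(), outputs = character()) {
  stopifnot(is.character(command), length(command) == 1L, is.list(config))
  structure(list(command = command, config_snapshot = config, seed = seed,
                 input_paths = inputs, output_paths = outputs,
                 package_version =
                   as.character(utils::packageVersion("fretsense"))),
            class = "run_manifest")
}

flatten_fields <- function(x, prefix = "") {
  out <- character()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(v)) {
      out <- c(out, flatten_fields(v, key))
    } else if (is.numeric(v)) {
      out <- c(out, sprintf("%s = %s (%s)", key,
                            paste(sprintf("%.17g", v), collapse = ", "),
                            paste(signif(v, 6), collapse = ", ")))
    } else if (length(v) > 0) {
      out <- c(out, sprintf("%s = %s", key, paste(as.character(v),
                                                  collapse = ", ")))
    }
  }
  out
}

#' Write a flat key/value report
#'
#' Serializes any of the package's result objects (calibration, binding
#' fit, FRET parameters, ...) plus a [run_manifest()] to a plain-text
#' key/value file.  Floating-point fields carry full precision
#' (17 significant digits) with a 6-digit display value in parentheses.
#'
#' @param result A named list or one of the package result objects.
#' @param path Output file path.
#' @param manifest A `run_manifest`, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, manifest = NULL) {
  lines <- flatten_fields(unclass(result))
  if (!is.null(manifest)) {
    stopifnot(inherits(manifest, "run_manifest"))
    lines <- c(lines, "", flatten_fields(unclass(manifest), "manifest"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Save / load a synthetic experiment configuration
#'
#' Configurations (including presets) round-trip through YAML so that a
#' simulated experiment is fully described by one text artifact.
#'
#' @param config A `synthetic_config` or preset parameter list.
#' @param path YAML file path.
#' @return `write_run_config`: `path`, invisibly.  `read_run_config`: the
#'   configuration; a serialized `synthetic_config` is revalidated through
#'   [synthetic_config()].
#' @export
write_run_config <- function(config, path) {
  x <- rapply(unclass(config), unclass, how = "replace")
  attr(x, "is_synthetic_config") <- NULL
  yaml::write_yaml(c(list(.class = class(config)[1]), x), path,
                   precision = 17)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "synthetic_config")) {
    as_band <- function(b) band_model(b$center, b$sigma, b$amplitude)
    return(synthetic_config(
      donor_bands = lapply(x$donor_bands, as_band),
      acceptor_absorption = as_band(x$acceptor_absorption),
      acceptor_emission = as_band(x$acceptor_emission),
      binding_K = x$binding_K, planted_E = x$planted_E,
      donor_conc = x$donor_conc,
      acceptor_concs = as.numeric(x$acceptor_concs),
      noise_sigma = x$noise_sigma, seed = x$seed,
      acceptor_direct_excitation = x$acceptor_direct_excitation,
      transfer_gain = x$transfer_gain, excitation = x$excitation,
      grid = as.numeric(x$grid)))
  }
  x
}
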