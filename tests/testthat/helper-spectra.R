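# Fixture builders used across test files.

gauss_spectrum <- function(center, sigma, amplitude = 1,
                           grid = seq(200, 800, by = 1),
                           kind = "emission") {
  spectrum(grid, amplitude * exp(-(grid - center)^2 / (2 * sigma^2)), kind)
}

write_temp_spectrum <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
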