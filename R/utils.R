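# Internal helpers shared across modules.

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.  seed = NULL means "use the ambient stream" (for Monte-Carlo
# drivers that seed once at the top).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coefficient of determination without summary.lm (which warns on
# numerically perfect fits).
r_squared_of <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

stop_invariant <- function(...) {
  stop(..., call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
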