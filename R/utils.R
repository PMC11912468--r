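# Internal helpers shared across modules.

# Run expr with a locally seeded RNG; the caller's RNG state is untouched.
# seed = NULL leaves the global stream alone (still restores nothing).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("%s must be a single positive finite number", name))
  }
  invisible(x)
}

# Trapezoidal integral of y over x (thin wrapper so the choice of rule is
# centralized).
trapz_int <- function(x, y) pracma::trapz(x, y)

# Linear interpolation that returns 0 outside the support, used when
# resampling densities onto a common grid.
interp_zero <- function(x, y, xout) {
  out <- stats::approx(x, y, xout = xout, rule = 1)$y
  out[is.na(out)] <- 0
  out
}
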