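#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state on exit, so seeded helpers never perturb the
#' session RNG stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Wrap an angle to (-pi, pi]
#'
#' @param a numeric vector of angles in radians.
#' @return Angles wrapped to the half-open interval (-pi, pi].
#' @export
#' @examples
#' wrap_angle(3 * pi / 2)  # -pi/2
wrap_angle <- function(a) {
  a - 2 * pi * ceiling((a - pi) / (2 * pi))
}

# Circular mean of a vector of angles; NA if the resultant is ~0.
circ_mean <- function(a) {
  s <- sum(sin(a)); c <- sum(cos(a))
  if (sqrt(s^2 + c^2) < 1e-12 * length(a)) return(NA_real_)
  atan2(s, c)
}

# Circular standard deviation, sqrt(-2 log Rbar).
circ_sd <- function(a) {
  r <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  r <- min(max(r, 1e-12), 1)
  sqrt(-2 * log(r))
}

# Unwrap a phase sequence (remove 2*pi jumps), base-R port of the usual rule.
unwrap_angle <- function(a) {
  if (length(a) < 2) return(a)
  d <- diff(a)
  jump <- -2 * pi * round(d / (2 * pi))
  a + c(0, cumsum(jump))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
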