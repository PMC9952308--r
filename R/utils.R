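# Internal helpers shared across modules.

SPEED_OF_LIGHT <- 299792458

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded simulation calls
#' do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite integer", call. = FALSE)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Reject non-finite or otherwise invalid scalar parameters by name
#' @noRd
check_finite_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("parameter '%s' must be a single finite number", name),
         call. = FALSE)
  if (x < min || x > max)
    stop(sprintf("parameter '%s' = %g outside allowed range [%g, %g]",
                 name, x, min, max), call. = FALSE)
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Root-mean-square of a numeric vector
#' @noRd
rms <- function(x) sqrt(mean(x^2))

#' Decibel helper (power ratio)
#' @noRd
db10 <- function(ratio) 10 * log10(ratio)
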