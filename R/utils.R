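# Internal helpers: unit conversions and seeded evaluation.

# Interface units are um / ml/min; SI is used internally.
.um_to_m <- function(x) x * 1e-6
.mlmin_to_m3s <- function(q) q * 1e-6 / 60

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded package operations never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic sub-stream seeds derived from one root seed. Kept below
# 2^31 so the result is always a valid R integer seed.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %%
               .Machine$integer.max)
}

.assertPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}

.assertNonNegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
  invisible(x)
}

#' Cell class labels
#'
#' The four event labels used throughout the package: the three biological
#' subpopulations of the erythroid differentiation end product plus debris.
#'
#' @return character vector `c("enucleated", "nucleated", "nucleus", "debris")`.
#' @export
cellClassLevels <- function() c("enucleated", "nucleated", "nucleus", "debris")

# The three biological (non-debris) classes.
.bioClasses <- function() c("enucleated", "nucleated", "nucleus")
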