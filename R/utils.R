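#' Expand one run seed into per-stage child seeds
#'
#' All stochastic stages derive their seed from a single run seed by fixed
#' offsets, so each stage is individually reproducible.
#'
#' @param seed integer run seed.
#' @return named list of integer child seeds.
#' @export
stage_seeds <- function(seed) {
  seed <- as.integer(seed)
  list(
    tree        = (seed + 101L) %% .Machine$integer.max,
    optima      = (seed + 202L) %% .Machine$integer.max,
    communities = (seed + 303L) %% .Machine$integer.max,
    soil        = (seed + 404L) %% .Machine$integer.max,
    assembly    = (seed + 505L) %% .Machine$integer.max,
    network     = (seed + 606L) %% .Machine$integer.max,
    permutation = (seed + 707L) %% .Machine$integer.max
  )
}

# run expr with a locally-set RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# z-score with population standard deviation (divide by n); errors on a
# constant vector rather than returning NaN
zscore_pop <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2) stop("zscore needs at least two values")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop("constant vector: zero standard deviation")
  (x - mu) / sigma
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
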