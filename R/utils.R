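`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Canonical name for a pairwise interaction feature
#'
#' Interaction features are named `"A::B"` with the two covariate names in
#' lexicographic order, so the same pair always maps to the same feature name.
#'
#' @param a,b Character vectors of covariate names (recycled pairwise).
#' @return Character vector of canonical `"A::B"` names.
#' @export
interaction_name <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste0(lo, "::", hi)
}

#' Hill tail-exponent estimator
#'
#' Estimates the power-law exponent alpha of a heavy-tailed sample (density
#' proportional to x^-alpha above `xmin`) as `1 + k / sum(log(x_i / xmin))`
#' over the k observations at or above `xmin`. Used to check the clone-size
#' law of simulated TCR repertoires.
#'
#' @param x Positive numeric sample (e.g. clone sizes).
#' @param xmin Tail threshold; only values `>= xmin` enter the estimate.
#' @return Estimated exponent (scalar).
#' @export
hill_exponent <- function(x, xmin = 10) {
  tail_x <- x[x >= xmin]
  if (length(tail_x) < 10) stop("fewer than 10 tail observations above xmin")
  1 + length(tail_x) / sum(log(tail_x / xmin))
}

# Run an expression under a locally-seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
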