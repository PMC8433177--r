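#' @keywords internal
"_PACKAGE"

## Ordered fibrosis stage scale: normal histology precedes the NASH CRN
## stages F0 (no fibrosis) .. F4 (cirrhosis).
STAGE_LEVELS <- c("N", "F0", "F1", "F2", "F3", "F4")

## Numeric regression targets for the stages (normal = -1, F0..F4 = 0..4),
## affine in stage order.
STAGE_TARGETS <- c(N = -1, F0 = 0, F1 = 1, F2 = 2, F3 = 3, F4 = 4)

#' Ordered fibrosis stage factor
#'
#' Coerces a character/factor vector to the package's ordered stage scale
#' `N < F0 < F1 < F2 < F3 < F4`.
#'
#' @param x character or factor vector of stage labels.
#' @return an ordered factor.
#' @export
stage_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), STAGE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown fibrosis stage label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = STAGE_LEVELS, ordered = TRUE)
}

## Numeric stage coding 0..5 used by the ordinal models and rank statistics.
stage_numeric <- function(x) as.integer(stage_factor(x)) - 1L

## Kendall rank correlation (tau-b, as stats::cor computes with ties).
kendall_tau <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok], method = "kendall")
}

#' Goodman-Kruskal gamma (rank concordance ignoring tied pairs)
#'
#' `(C - D) / (C + D)` over pairs untied on both variables. Unlike Kendall
#' tau-b, gamma reaches 1 for a continuous score perfectly concordant with a
#' tied ordinal grade: tau-b is capped below 1 by the grade's tie structure
#' (`sqrt((n0 - T) / n0)`), so "perfect ranking" assertions use gamma.
#'
#' @param x,y numeric vectors.
#' @return gamma in `[-1, 1]` (`NA` if no untied pairs).
#' @export
rank_concordance <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  dx <- sign(outer(x, x, "-"))[lower.tri(matrix(0, n, n))]
  dy <- sign(outer(y, y, "-"))[lower.tri(matrix(0, n, n))]
  s <- dx * dy
  C <- sum(s > 0); D <- sum(s < 0)
  if (C + D == 0) return(NA_real_)
  (C - D) / (C + D)
}

## One Dirichlet draw per row of the alpha matrix.
rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha, rate = 1),
              nrow = nrow(alpha), dimnames = dimnames(alpha))
  sweep(g, 1, rowSums(g), "/")
}

## Deterministic sub-seeds for pipeline stages, all below 2^31.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed %% 2147483646L))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

## Run expr under a local seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
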