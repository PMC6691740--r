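#' cavebiome: cave microbiome community analysis
#'
#' Diversity, ordination, indicator-taxon and co-occurrence network analysis
#' for habitat-resolved (air / water / rock / sediment) microbial count
#' tables, plus a synthetic-community generator with planted ground truth.
#'
#' @keywords internal
"_PACKAGE"

#' Fixed niche levels used throughout the package
#'
#' Cave samples belong to one of four substrate niches.
#' @export
CAVE_NICHES <- c("air", "water", "rock", "sediment")

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a root seed and a stage name
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' receives a child seed obtained by stable (platform-independent) hashing of
#' the stage name, so stages can be re-run in isolation.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + as.numeric(seed) %% 2147483647) %% 2147483647)
}

## assert helper: stop with a formatted message
abort_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

#' Adjusted Rand index between two partitions
#'
#' Agreement between two labelings of the same items, corrected for chance.
#' Used to score recovered network modules against planted correlation blocks.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## Spearman rho via midranks + Pearson, with two-sided t-approximation p.
## Shared by the correlation screen and the network correlation matrix.
spearman_rho_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) return(c(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  c(rho = rho, p = p, n = n)
}
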