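## Ordination and distance-based inference.

#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering `B = -1/2 J D^2 J` followed by eigendecomposition.
#' Coordinates are returned for positive eigenvalues only (scaled by the
#' square root of the eigenvalue); negative eigenvalues are reported
#' uncorrected, and the proportion explained is relative to the sum of
#' positive eigenvalues.
#'
#' @param d a [dist_matrix] (or symmetric matrix / `dist`).
#' @param n_axes maximum number of axes to return (default: all positive).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `proportion_explained`.
#' @export
pcoa <- function(d, n_axes = NULL) {
  m <- as.matrix(d)
  abort_if(nrow(m) < 2, "PCoA needs at least 2 samples")
  abort_if(!isTRUE(all.equal(m, t(m), tolerance = 1e-8)),
           "distance matrix is not symmetric")
  n <- nrow(m)
  D2 <- m^2
  # J D2 J without forming J: subtract row/column means, add grand mean
  rm_ <- rowMeans(D2); gm <- mean(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-12
  pos <- which(ev > tol)
  if (!is.null(n_axes)) pos <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), length(pos))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 proportion_explained = ev[pos] / sum(ev[ev > tol])),
            class = "pcoa_result")
}

## One-way pseudo-F from a squared-distance matrix and integer group codes.
pseudo_F <- function(D2, gi, k, n) {
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (g in seq_len(k)) {
    idx <- which(gi == g)
    ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix:
#' pseudo-F from between/within sums of squared distances; the p-value is the
#' permutation tail probability `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`
#' under random relabeling.
#'
#' @param d a [dist_matrix] (or symmetric matrix / `dist`).
#' @param groups group label per sample; >= 2 groups of >= 2 samples each.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed.
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `grouping`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L,
                      grouping = deparse(substitute(groups))) {
  m <- as.matrix(d)
  n <- nrow(m)
  stopifnot(length(groups) == n)
  gf <- factor(groups)
  k <- nlevels(gf)
  abort_if(k < 2, "need at least 2 groups")
  abort_if(any(table(gf) < 2), "every group needs >= 2 samples")
  D2 <- m^2
  gi <- as.integer(gf)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (g in seq_len(k)) {
    idx <- which(gi == g)
    ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  }
  f_obs <- ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  r2 <- (sst - ssw) / sst
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      pseudo_F(D2, gi[sample.int(n)], k, n) >= f_obs
    }, logical(1)))
  })
  structure(list(pseudo_F = f_obs, R2 = r2,
                 p_value = (1 + count) / (1 + n_perm),
                 n_permutations = n_perm, grouping = grouping,
                 df = c(between = k - 1L, within = n - k)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$grouping, x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Fit an environmental variable onto ordination axes
#'
#' `R2` is the coefficient of determination of the least-squares regression
#' of the (centered) variable on the first `k_axes` ordination axes; the
#' direction is the unit vector of fitted coefficients; significance is a
#' permutation tail probability of `R2` under shuffling of the variable.
#' Samples with `NA` in the variable are dropped for this variable only.
#'
#' @param ord a `pcoa_result` (or a coordinates matrix).
#' @param values numeric variable, one value per ordination sample.
#' @param k_axes number of leading axes to fit on (default 2).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param variable name used in the output.
#' @return list of class `envfit_result`: `variable`, `direction`, `R2`,
#'   `p_value`, `n`.
#' @export
envfit_axes <- function(ord, values, k_axes = 2, n_perm = 999, seed = 1L,
                        variable = deparse(substitute(values))) {
  coords <- if (inherits(ord, "pcoa_result")) ord$coordinates else as.matrix(ord)
  stopifnot(length(values) == nrow(coords))
  abort_if(k_axes > ncol(coords), "k_axes exceeds available axes (%d)",
           ncol(coords))
  ok <- is.finite(values)
  X <- coords[ok, seq_len(k_axes), drop = FALSE]
  y <- values[ok]
  n <- length(y)
  abort_if(n < k_axes + 2, "too few non-missing observations (%d)", n)
  abort_if(stats::sd(y) == 0, "variable '%s' is constant", variable)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qr_ <- qr(Xc)
  Q <- qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  r2_of <- function(yv) {
    yc <- yv - mean(yv)
    sum(crossprod(Q, yc)^2) / sum(yc^2)
  }
  r2 <- r2_of(y)
  beta <- qr.coef(qr(cbind(1, Xc)), y)[-1]
  beta[is.na(beta)] <- 0
  dir <- if (sum(beta^2) > 0) beta / sqrt(sum(beta^2)) else beta
  count <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(b) r2_of(y[sample.int(n)]) >= r2, logical(1)))
  })
  structure(list(variable = variable, direction = dir, R2 = r2,
                 p_value = (1 + count) / (1 + n_perm), n = n,
                 k_axes = k_axes),
            class = "envfit_result")
}

#' Spearman rank-correlation screen of alpha diversity against factors
#'
#' For each environmental variable, the Spearman correlation (midranks) of a
#' per-sample response — by default the Shannon index — with that variable,
#' with a two-sided p from the t approximation
#' `t = rho sqrt((n-2) / (1-rho^2))`. Samples with `NA` in a variable are
#' dropped for that variable only; fewer than 4 pairs gives `NA` with a
#' warning.
#'
#' @param alpha data.frame from [alpha_diversity] (needs `sample_id` and the
#'   response column).
#' @param meta a [sample_metadata].
#' @param variables metadata columns to screen (default: the standard factor
#'   set).
#' @param response column of `alpha` to correlate (default `"shannon"`).
#' @param adjust add a Benjamini-Hochberg `p_adj` column (default `TRUE`).
#' @return data.frame: `variable`, `rho`, `p_value`, `n` (and `p_adj`).
#' @export
rank_correlation_screen <- function(alpha, meta,
                                    variables = c("depth_m", "temperature",
                                                  "air_humidity", "pH",
                                                  "TOC", "TN", "moisture"),
                                    response = "shannon", adjust = TRUE) {
  stopifnot(response %in% names(alpha))
  meta <- meta[match(alpha$sample_id, meta$sample_id), , drop = FALSE]
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    if (is.null(x)) return(data.frame(variable = v, rho = NA_real_,
                                      p_value = NA_real_, n = 0L))
    res <- spearman_rho_p(as.numeric(x), alpha[[response]])
    if (is.na(res[["rho"]]) && res[["n"]] < 4L)
      warning(sprintf("variable '%s': fewer than 4 paired observations", v),
              call. = FALSE)
    data.frame(variable = v, rho = res[["rho"]], p_value = res[["p"]],
               n = as.integer(res[["n"]]))
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
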