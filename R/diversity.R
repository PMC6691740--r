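## Alpha diversity, beta dissimilarity, beta partitioning, Venn counts.

#' Shannon diversity of one sample (natural log)
#' @param x non-negative counts or abundances with a positive sum.
#' @return `H = -sum p_i ln p_i` over nonzero proportions.
#' @export
shannon <- function(x) {
  abort_if(sum(x) <= 0, "Shannon undefined for an all-zero sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Chao1 richness estimator of one sample
#'
#' Classic: `S_obs + F1^2 / (2 F2)` (falling back to
#' `S_obs + F1 (F1 - 1) / 2` when there are no doubletons); bias-corrected:
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`. `F1`, `F2` are singleton and
#' doubleton counts, so the input must be integer counts.
#'
#' @param x integer counts with a positive sum.
#' @param bias_corrected logical.
#' @return estimated richness (>= observed richness).
#' @export
chao1 <- function(x, bias_corrected = FALSE) {
  abort_if(sum(x) <= 0, "Chao1 undefined for an all-zero sample")
  s_obs <- sum(x > 0)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (bias_corrected) return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Good's coverage of one sample
#' @param x integer counts with a positive sum.
#' @return `1 - F1 / N`: estimated fraction of the community sampled.
#' @export
goods_coverage <- function(x) {
  n <- sum(x)
  abort_if(n <= 0, "coverage undefined for an all-zero sample")
  1 - sum(x == 1) / n
}

#' Per-sample alpha diversity table
#'
#' Conventionally computed on rarefied counts so richness estimators are
#' comparable across samples.
#'
#' @param t a [count_table] or integer-valued [abundance_table].
#' @param bias_corrected passed to [chao1].
#' @return data.frame with `sample_id`, `observed_otus`, `chao1`, `shannon`,
#'   `goods_coverage`.
#' @export
alpha_diversity <- function(t, bias_corrected = FALSE) {
  m <- unclass(as.matrix(t))
  data.frame(
    sample_id = rownames(m),
    observed_otus = apply(m, 1L, function(x) sum(x > 0)),
    chao1 = apply(m, 1L, chao1, bias_corrected = bias_corrected),
    shannon = apply(m, 1L, shannon),
    goods_coverage = apply(m, 1L, goods_coverage),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y)`.
#'
#' @param t abundance or count matrix, samples in rows (>= 2 samples).
#' @return a [dist_matrix].
#' @export
bray_curtis <- function(t) {
  m <- unclass(as.matrix(t))
  abort_if(nrow(m) < 2, "need at least 2 samples")
  rs <- rowSums(m)
  abort_if(any(rs == 0), "Bray-Curtis undefined for all-zero sample '%s'",
           rownames(m)[rs == 0][1])
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    # vectorized over the remaining rows
    mins <- pmin(m[rep(i, n - i), , drop = FALSE],
                 m[(i + 1L):n, , drop = FALSE])
    d[i, (i + 1L):n] <- 1 - 2 * rowSums(mins) / (rs[i] + rs[(i + 1L):n])
  }
  dist_matrix(d + t(d), metric = "bray_curtis")
}

## Per-branch descendant abundance fractions: edges x samples matrix where
## entry (e, s) is the fraction of sample s's total abundance carried by
## tips descending from edge e.
branch_fractions <- function(m, tree) {
  miss <- setdiff(colnames(m), tree$tip.label)
  abort_if(length(miss) > 0, "taxa missing from tree: %s",
           paste(utils::head(miss, 10), collapse = ", "))
  rel <- m / rowSums(m)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # node x sample accumulation in postorder
  acc <- matrix(0, nnode, nrow(m))
  idx <- match(tree$tip.label, colnames(rel))
  has <- !is.na(idx)
  acc[seq_len(ntip)[has], ] <- base::t(rel[, idx[has], drop = FALSE])
  er <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(er$edge))) {
    p <- er$edge[k, 1]; ch <- er$edge[k, 2]
    acc[p, ] <- acc[p, ] + acc[ch, ]
  }
  list(frac = acc[tree$edge[, 2], , drop = FALSE],  # one row per edge
       len = tree$edge.length)
}

#' Weighted UniFrac dissimilarity matrix
#'
#' Raw: `sum_b l_b |A_b - B_b|` over branches, with `A_b` the fraction of
#' sample A's abundance descending from branch b. The normalized variant
#' divides by `sum_b l_b (A_b + B_b)` and is bounded in `[0, 1]`.
#'
#' @param t abundance or count matrix, samples in rows; every taxon must be a
#'   tip of `tree`.
#' @param tree rooted ape `phylo` with branch lengths.
#' @param normalized logical; default `TRUE` (bounded, ordination-friendly).
#' @return a [dist_matrix].
#' @export
weighted_unifrac <- function(t, tree, normalized = TRUE) {
  m <- unclass(as.matrix(t))
  abort_if(nrow(m) < 2, "need at least 2 samples")
  validate_tree(tree)
  bf <- branch_fractions(m, tree)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    ai <- bf$frac[, i]
    for (j in (i + 1L):n) {
      num <- sum(bf$len * abs(ai - bf$frac[, j]))
      if (normalized) {
        den <- sum(bf$len * (ai + bf$frac[, j]))
        d[i, j] <- if (den > 0) num / den else 0
      } else d[i, j] <- num
    }
  }
  dist_matrix(d + t(d),
              metric = if (normalized) "wunifrac" else "wunifrac_raw")
}

#' Sorensen beta-diversity partition for one sample pair
#'
#' Partitions total Sorensen dissimilarity into species turnover
#' (Simpson dissimilarity) and nestedness/richness-difference components:
#' with `a` shared species and `b`, `c` the uniques,
#' `beta_sor = (b + c) / (2a + b + c)`,
#' `beta_sim = min(b, c) / (a + min(b, c))`, `beta_sne = beta_sor - beta_sim`.
#'
#' @param x,y presence/absence (or count) vectors over the same taxa; each
#'   must have at least one presence.
#' @return named numeric: `beta_sor`, `beta_sim`, `beta_sne`.
#' @export
beta_partition_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  px <- x > 0; py <- y > 0
  abort_if(!any(px) || !any(py), "each community must have >= 1 species")
  a <- sum(px & py)
  b <- sum(px & !py)
  c_ <- sum(!px & py)
  beta_sor <- if (a + b + c_ == 0) 0 else (b + c_) / (2 * a + b + c_)
  beta_sim <- if (a + min(b, c_) == 0) 0 else min(b, c_) / (a + min(b, c_))
  c(beta_sor = beta_sor, beta_sim = beta_sim, beta_sne = beta_sor - beta_sim)
}

#' Pairwise beta-diversity partition across all samples
#' @param t presence/abundance matrix, samples in rows.
#' @return data.frame with one row per unordered sample pair.
#' @export
beta_partition <- function(t) {
  m <- unclass(as.matrix(t))
  n <- nrow(m)
  abort_if(n < 2, "need at least 2 samples")
  pairs <- utils::combn(n, 2)
  res <- apply(pairs, 2L, function(ij) beta_partition_pair(m[ij[1], ],
                                                           m[ij[2], ]))
  data.frame(sample_a = rownames(m)[pairs[1, ]],
             sample_b = rownames(m)[pairs[2, ]],
             base::t(res), row.names = NULL, stringsAsFactors = FALSE)
}

#' Exclusive and shared OTU counts across niches (Venn regions)
#'
#' An OTU is present in a niche iff it has a count > 0 in at least one sample
#' of that niche. Returns, for every nonempty subset of niches, the number of
#' OTUs detected in exactly that subset (the Venn regions, which sum to the
#' total number of detected OTUs).
#'
#' @param t a [count_table] or abundance matrix.
#' @param groups vector of niche labels, one per sample (row) of `t`.
#' @return data.frame with columns `subset` (niches joined by `&`), `n_niches`
#'   and `n_otus`.
#' @export
venn_counts <- function(t, groups) {
  m <- unclass(as.matrix(t))
  stopifnot(length(groups) == nrow(m))
  lev <- unique(groups)
  abort_if(length(lev) < 2, "need at least 2 groups")
  pres <- vapply(lev, function(g)
    colSums(m[groups == g, , drop = FALSE] > 0) > 0, logical(ncol(m)))
  detected <- rowSums(pres) > 0
  pattern <- apply(pres[detected, , drop = FALSE], 1L,
                   function(z) paste(lev[z], collapse = "&"))
  k <- length(lev)
  subsets <- unlist(lapply(seq_len(k), function(size)
    utils::combn(lev, size, FUN = paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  counts <- as.integer(table(factor(pattern, levels = subsets)))
  data.frame(subset = subsets,
             n_niches = lengths(strsplit(subsets, "&", fixed = TRUE)),
             n_otus = counts, stringsAsFactors = FALSE)
}
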