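## Indicator-taxon analysis (IndVal) and focus-niche enrichment
## classification.

#' IndVal indicator analysis with permutation test
#'
#' For taxon t and group g: specificity `A = mean abundance in g / sum of
#' group mean abundances`, fidelity `B = fraction of g's samples where t is
#' present`; the indicator statistic is `sqrt(A * B)` (the group-equalized
#' IndVal.g). Each taxon is reported against its best single group (argmax of
#' the statistic), with a permutation p-value
#' `(1 + #{stat_perm >= stat_obs}) / (1 + n_perm)` under group-label
#' shuffling. A taxon is flagged an indicator when `indval > stat_threshold`
#' and `p < p_threshold`.
#'
#' @param t abundance matrix ([count_table] or [abundance_table]), samples in
#'   rows.
#' @param groups group label per sample; >= 2 groups with >= 2 samples each.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param stat_threshold,p_threshold indicator flagging thresholds
#'   (defaults 0.6 and 0.05).
#' @return data.frame with one row per taxon: `taxon_id`, `group`, `A`, `B`,
#'   `indval`, `p_value`, `is_indicator`. Taxa with zero abundance everywhere
#'   are skipped (recorded in attribute `skipped`).
#' @export
indval <- function(t, groups, n_perm = 999, seed = 1L,
                   stat_threshold = 0.6, p_threshold = 0.05) {
  X <- unclass(as.matrix(t))
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(length(groups) == n)
  gf <- factor(groups)
  k <- nlevels(gf)
  abort_if(k < 2, "need at least 2 groups")
  abort_if(any(table(gf) < 2), "every group needs >= 2 samples")
  skipped <- colnames(X)[colSums(X) == 0]
  if (length(skipped) > 0)
    X <- X[, colSums(X) > 0, drop = FALSE]
  abort_if(ncol(X) == 0, "no taxon with nonzero abundance")
  gi <- as.integer(gf)
  ng <- tabulate(gi, k)
  pres <- (X > 0) + 0

  stat_matrix <- function(perm_gi) {
    M <- rowsum(X, perm_gi) / ng          # k x T group mean abundance
    A <- sweep(M, 2L, colSums(M), "/")
    B <- rowsum(pres, perm_gi) / ng
    sqrt(A * B)
  }
  S <- stat_matrix(gi)
  best <- max.col(base::t(S), ties.method = "first")
  obs <- S[cbind(best, seq_len(ncol(S)))]
  M <- rowsum(X, gi) / ng
  A_obs <- (M / rep(colSums(M), each = k))[cbind(best, seq_len(ncol(S)))]
  B_obs <- (rowsum(pres, gi) / ng)[cbind(best, seq_len(ncol(S)))]

  count <- rep(0L, ncol(X))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Sp <- stat_matrix(gi[sample.int(n)])
      mx <- do.call(pmax, lapply(seq_len(k), function(g) Sp[g, ]))
      count <- count + (mx >= obs - 1e-12)
    }
  })
  p <- (1 + count) / (1 + n_perm)
  out <- data.frame(taxon_id = colnames(X), group = levels(gf)[best],
                    A = A_obs, B = B_obs, indval = obs, p_value = p,
                    is_indicator = obs > stat_threshold & p < p_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Classify OTUs as enriched/depleted in a focus niche
#'
#' A permutation test on `log2(CPM + 1)`: the observed statistic per OTU is
#' the mean in the focus niche minus the mean elsewhere; the p-value is the
#' two-sided permutation tail over sample-label shuffles, adjusted across
#' OTUs by Benjamini-Hochberg. An OTU is `enriched` (`depleted`) when
#' `q < alpha` and its log2 fold change of CPM means (pseudocount 1) is
#' positive (negative), else `unchanged`.
#'
#' @param t a [count_table] (OTUs in columns).
#' @param meta a [sample_metadata] covering the samples of `t`.
#' @param focus_niche niche compared against all others (default `"air"`).
#' @param n_perm permutations (default 2000).
#' @param alpha FDR level (default 0.05).
#' @param seed integer seed.
#' @return data.frame per OTU: `otu_id`, `mean_logcpm`, `logFC`, `p_value`,
#'   `q_value`, `class`. OTUs absent everywhere are skipped.
#' @export
classify_enrichment <- function(t, meta, focus_niche = "air", n_perm = 2000,
                                alpha = 0.05, seed = 1L) {
  stopifnot(inherits(t, "count_table"))
  meta <- align_metadata(t, meta)
  f <- meta$niche == focus_niche
  abort_if(sum(f) < 3 || sum(!f) < 3,
           "focus niche and complement each need >= 3 samples")
  keep <- colSums(t) > 0
  cpm <- unclass(to_cpm(unclass(t)[, keep, drop = FALSE]))
  L <- log2(cpm + 1)
  n <- nrow(L)
  n1 <- sum(f); n0 <- n - n1
  w_of <- function(ff) ff / n1 - (!ff) / n0
  obs <- drop(crossprod(w_of(f), L))
  # vectorized permutation weights: one column per shuffle
  W <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) w_of(f[sample.int(n)]), numeric(n))
  })
  perm <- crossprod(W, L)                        # n_perm x T
  count <- colSums(sweep(abs(perm), 2L, abs(obs) - 1e-12, ">="))
  p <- (1 + count) / (1 + n_perm)
  q <- stats::p.adjust(p, method = "BH")
  logfc <- log2(colMeans(cpm[f, , drop = FALSE]) + 1) -
    log2(colMeans(cpm[!f, , drop = FALSE]) + 1)
  cls <- rep("unchanged", ncol(L))
  cls[q < alpha & logfc > 0] <- "enriched"
  cls[q < alpha & logfc < 0] <- "depleted"
  data.frame(otu_id = colnames(L), mean_logcpm = colMeans(L),
             logFC = logfc, p_value = p, q_value = q, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
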