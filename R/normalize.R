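## Table-level filters and normalizations.

#' Discard rare OTUs by whole-table relative abundance
#'
#' An OTU is kept iff its total count divided by the table's total count is
#' at least `threshold` (the conventional 1e-5 whole-dataset filter).
#'
#' @param t a [count_table].
#' @param threshold proportion in (0, 1).
#' @return filtered [count_table].
#' @export
filter_rare_otus <- function(t, threshold = 1e-5) {
  stopifnot(inherits(t, "count_table"))
  abort_if(threshold <= 0 || threshold >= 1, "threshold must be in (0,1)")
  tot <- sum(as.numeric(t))
  keep <- colSums(t) / tot >= threshold
  abort_if(!any(keep), "no OTU survives the abundance filter")
  count_table(unclass(t)[, keep, drop = FALSE],
              provenance = attr(t, "provenance"))
}

#' Rarefy samples to a common depth
#'
#' Each sample is subsampled without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples with fewer than `depth`
#' reads are dropped with a warning. Deterministic under `seed`; per-sample
#' draws use child seeds keyed by sample id, so the draw for a sample does
#' not depend on the order or presence of other samples, and permuting taxa
#' commutes with rarefaction (taxa are processed in a canonical sorted order
#' internally).
#'
#' @param t a [count_table].
#' @param depth target reads per sample; default is the minimum sample total.
#' @param seed integer seed.
#' @return an [abundance_table] with method `"rarefied"` (integer-valued).
#' @export
rarefy <- function(t, depth = NULL, seed = 1L) {
  stopifnot(inherits(t, "count_table"))
  if (is.null(depth)) depth <- min(rowSums(t))
  abort_if(depth < 1, "rarefaction depth must be >= 1")
  totals <- rowSums(t)
  drop <- totals < depth
  if (any(drop))
    warning(sprintf("dropping %d sample(s) below depth %d: %s", sum(drop),
                    depth, paste(utils::head(rownames(t)[drop], 5),
                                 collapse = ", ")), call. = FALSE)
  m <- unclass(t)[!drop, , drop = FALSE]
  abort_if(nrow(m) == 0, "no sample reaches rarefaction depth %d", depth)
  ord <- order(colnames(m))           # canonical taxon order for the draws
  out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    row <- m[i, ord]
    drawn <- with_seed(child_seed(seed, rownames(m)[i]), {
      # expand-and-sample is exact multivariate hypergeometric
      reads <- rep.int(seq_along(row), row)
      picked <- sample(reads, depth, replace = FALSE)
      tabulate(picked, nbins = length(row))
    })
    out[i, ord] <- drawn
  }
  abundance_table(out, method = "rarefied")
}

#' Cumulative sum scaling (CSS) normalization
#'
#' Per sample j, the scaling factor `s_j` is the sum of that sample's counts
#' that are less than or equal to the q-th quantile of its nonzero counts
#' (lower empirical quantile, type 1). Output is `counts / s_j * 1000`.
#'
#' @param t a [count_table].
#' @param quantile quantile of the nonzero count distribution, default 0.5.
#' @return an [abundance_table] with method `"css"`; attribute
#'   `scaling_factors` records `s_j`.
#' @export
css_normalize <- function(t, quantile = 0.5) {
  stopifnot(inherits(t, "count_table"))
  abort_if(quantile <= 0 || quantile > 1, "quantile must be in (0,1]")
  m <- unclass(t)
  storage.mode(m) <- "double"
  s <- vapply(seq_len(nrow(m)), function(i) {
    nz <- m[i, m[i, ] > 0]
    q <- stats::quantile(nz, probs = quantile, type = 1, names = FALSE)
    sum(m[i, m[i, ] <= q])
  }, 0)
  bad <- s <= 0
  abort_if(any(bad), "CSS scaling factor is zero for sample '%s'",
           rownames(m)[bad][1])
  out <- m / s * 1000
  res <- abundance_table(out, method = "css")
  attr(res, "scaling_factors") <- stats::setNames(s, rownames(m))
  res
}

#' Relative abundance (rows sum to 1)
#' @param t a [count_table] or numeric matrix with positive row sums.
#' @return an [abundance_table] with method `"relative"`.
#' @export
to_relative <- function(t) {
  m <- unclass(as.matrix(t))
  storage.mode(m) <- "double"
  rs <- rowSums(m)
  abort_if(any(rs <= 0), "sample '%s' has zero total", rownames(m)[rs <= 0][1])
  abundance_table(m / rs, method = "relative")
}

#' Counts per million
#' @param t a [count_table] or numeric matrix with positive row sums.
#' @return an [abundance_table] with method `"cpm"` (rows sum to 1e6).
#' @export
to_cpm <- function(t) {
  rel <- to_relative(t)
  abundance_table(unclass(rel) * 1e6, method = "cpm")
}

#' Aggregate an OTU table to genus level
#'
#' OTU counts sharing a genus label are summed. OTUs unassigned at genus are
#' pooled under `"<lowest-assigned-rank-name>__unclassified"` (so an OTU with
#' family but no genus aggregates as, e.g., `"FamilyX__unclassified"`).
#'
#' @param t a [count_table] (OTUs in columns).
#' @param tax a [taxonomy_map] covering every OTU of `t`.
#' @return a [count_table] with genus-level columns; attribute
#'   `genus_taxonomy` maps each output label to a representative lineage.
#' @export
aggregate_to_genus <- function(t, tax) {
  stopifnot(inherits(t, "count_table"), inherits(tax, "taxonomy_map"))
  miss <- setdiff(colnames(t), tax$taxon_id)
  abort_if(length(miss) > 0, "OTUs absent from taxonomy: %s",
           paste(utils::head(miss, 10), collapse = ", "))
  tx <- tax[match(colnames(t), tax$taxon_id), , drop = FALSE]
  label <- tx$genus
  for (i in which(label == "")) {
    lineage <- as.character(tx[i, TAX_RANKS])
    filled <- which(lineage != "")
    base <- if (length(filled) > 0) lineage[max(filled)] else "unassigned"
    label[i] <- paste0(base, "__unclassified")
  }
  groups <- factor(label, levels = unique(label))
  m <- rowsum(base::t(unclass(t)), groups)   # taxa x samples -> group sums
  out <- count_table(base::t(m), provenance = attr(t, "provenance"))
  rep_idx <- match(levels(groups), label)
  gt <- tx[rep_idx, , drop = FALSE]
  gt$taxon_id <- levels(groups)
  attr(out, "genus_taxonomy") <- taxonomy_map(gt)
  out
}
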