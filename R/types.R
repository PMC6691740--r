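## Domain containers. All are thin S3 wrappers over base matrices/data.frames
## so they interoperate with vegan/ape/igraph without conversion friction.

#' Construct and validate a count table
#'
#' The universal input of the pipeline: a non-negative integer matrix of
#' per-sample taxon abundances, stored samples x taxa.
#'
#' @param counts numeric matrix (samples in rows, taxa in columns) with
#'   dimnames, or coercible to one.
#' @param provenance free-text tag recording where the table came from.
#' @return an integer matrix of class `count_table`.
#' @export
count_table <- function(counts, provenance = "unspecified") {
  counts <- as.matrix(counts)
  abort_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "count_table requires sample (row) and taxon (column) names")
  abort_if(anyDuplicated(rownames(counts)) > 0,
           "duplicate sample id: %s",
           rownames(counts)[duplicated(rownames(counts))][1])
  abort_if(anyDuplicated(colnames(counts)) > 0,
           "duplicate taxon id: %s",
           colnames(counts)[duplicated(colnames(counts))][1])
  abort_if(any(!is.finite(counts)), "count table contains non-finite values")
  abort_if(any(counts < 0), "count table contains negative values")
  abort_if(any(abs(counts - round(counts)) > 1e-8),
           "count table contains non-integer values")
  rs <- rowSums(counts)
  abort_if(any(rs == 0), "sample '%s' has zero total count",
           rownames(counts)[rs == 0][1])
  storage.mode(counts) <- "integer"
  structure(counts, class = c("count_table", "matrix", "array"),
            provenance = provenance)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (total %s reads)\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Construct a normalized abundance table
#'
#' Same shape as a [count_table] but real valued, tagged with the
#' normalization that produced it.
#'
#' @param x numeric matrix, samples x taxa, with dimnames.
#' @param method one of `"relative"`, `"cpm"`, `"css"`, `"rarefied"`.
#' @return numeric matrix of class `abundance_table` with a `method` attribute.
#' @export
abundance_table <- function(x, method = c("relative", "cpm", "css", "rarefied")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  abort_if(is.null(rownames(x)) || is.null(colnames(x)),
           "abundance_table requires dimnames")
  abort_if(any(x < 0), "abundance table contains negative values")
  if (method == "relative")
    abort_if(any(abs(rowSums(x) - 1) > 1e-9),
             "relative abundance rows must sum to 1")
  structure(x, class = c("abundance_table", "matrix", "array"), method = method)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table (%s): %d samples x %d taxa\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a pairwise sample distance matrix
#'
#' @param m symmetric numeric matrix with zero diagonal and sample dimnames.
#' @param metric label of the dissimilarity used.
#' @return matrix of class `dist_matrix`.
#' @export
dist_matrix <- function(m, metric = "unknown") {
  m <- as.matrix(m)
  abort_if(nrow(m) != ncol(m), "distance matrix must be square")
  abort_if(is.null(rownames(m)), "distance matrix requires sample names")
  abort_if(!isTRUE(all.equal(m, t(m), tolerance = 1e-10)),
           "distance matrix is not symmetric")
  abort_if(any(abs(diag(m)) > 1e-12), "distance matrix diagonal must be zero")
  abort_if(any(m < -1e-12), "distances must be non-negative")
  m[m < 0] <- 0
  diag(m) <- 0
  m <- (m + t(m)) / 2
  colnames(m) <- rownames(m)
  structure(m, class = c("dist_matrix", "matrix", "array"), metric = metric)
}

#' Convert a `dist_matrix` to a base `dist` object
#' @param d a [dist_matrix].
#' @return a `stats::dist` object.
#' @export
as_dist <- function(d) stats::as.dist(unclass(d))

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Construct and validate a taxonomy map
#'
#' Seven-rank lineage per taxon. Missing ranks are empty strings and are only
#' permitted at the tail of the lineage (a genus without a family is invalid).
#'
#' @param df data.frame with column `taxon_id` plus the seven rank columns
#'   domain...species (missing trailing columns are added empty).
#' @return data.frame of class `taxonomy_map`.
#' @export
taxonomy_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  abort_if(!"taxon_id" %in% names(df), "taxonomy needs a taxon_id column")
  for (r in TAX_RANKS) if (!r %in% names(df)) df[[r]] <- ""
  df <- df[, c("taxon_id", TAX_RANKS)]
  for (r in TAX_RANKS) {
    df[[r]] <- as.character(df[[r]])
    df[[r]][is.na(df[[r]])] <- ""
  }
  abort_if(anyDuplicated(df$taxon_id) > 0, "duplicate taxon id in taxonomy: %s",
           df$taxon_id[duplicated(df$taxon_id)][1])
  ranks <- as.matrix(df[, TAX_RANKS])
  filled <- ranks != ""
  # a filled rank after a gap means an internal hole in the lineage
  bad <- apply(filled, 1L, function(z) {
    any(diff(as.integer(z)) > 0L)
  })
  abort_if(any(bad), "taxon '%s' has an internal gap in its lineage",
           df$taxon_id[bad][1])
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Construct and validate sample metadata
#'
#' One row per sample: cave id, niche (one of [CAVE_NICHES]), distance from
#' the cave entrance (`depth_m`), temperature (degrees C), air humidity (%),
#' and the substrate measurements pH, TOC, TN and moisture, which are `NA`
#' for niches where they are not measured (e.g. air).
#'
#' @param df data.frame with at least `sample_id`, `cave`, `niche`.
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "cave", "niche")
  miss <- setdiff(need, names(df))
  abort_if(length(miss) > 0, "metadata missing column(s): %s",
           paste(miss, collapse = ", "))
  abort_if(anyDuplicated(df$sample_id) > 0, "duplicate sample id: %s",
           df$sample_id[duplicated(df$sample_id)][1])
  bad <- !df$niche %in% CAVE_NICHES
  abort_if(any(bad), "sample '%s' has invalid niche '%s' (must be one of %s)",
           df$sample_id[bad][1], df$niche[bad][1],
           paste(CAVE_NICHES, collapse = "/"))
  for (v in c("depth_m", "temperature", "air_humidity", "pH", "TOC", "TN",
              "moisture"))
    if (!v %in% names(df)) df[[v]] <- NA_real_
  rownames(df) <- df$sample_id
  class(df) <- c("sample_metadata", "data.frame")
  df
}

## Check that every sample of a count table has a metadata row; return
## metadata reordered to the table's samples.
align_metadata <- function(t, meta) {
  miss <- setdiff(rownames(t), meta$sample_id)
  abort_if(length(miss) > 0, "samples missing from metadata: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  meta[match(rownames(t), meta$sample_id), , drop = FALSE]
}

## Validate an ape phylo as a usable phylogeny over taxa.
validate_tree <- function(tree) {
  abort_if(!inherits(tree, "phylo"), "tree must be an ape 'phylo' object")
  abort_if(anyDuplicated(tree$tip.label) > 0, "tree has duplicate tip labels")
  abort_if(is.null(tree$edge.length), "tree has no branch lengths")
  abort_if(any(!is.finite(tree$edge.length)),
           "tree has non-finite branch lengths")
  abort_if(any(tree$edge.length < 0), "tree has negative branch lengths")
  tree
}
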