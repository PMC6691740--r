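## TSV dialect: tab separated, UTF-8, "#" comment lines ignored, one header
## row. Count tables on disk may be taxa-in-rows (the common OTU-table export)
## or samples-in-rows; `orientation` declares which. Internally everything is
## samples x taxa.

read_tsv_raw <- function(path) {
  abort_if(!file.exists(path), "file not found: %s", path)
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "NA", fileEncoding = "UTF-8")
}

#' Read a count table from TSV
#'
#' @param path TSV file; first column holds ids, remaining columns integer
#'   counts.
#' @param orientation `"taxa_rows"` (default: rows are taxa, columns samples)
#'   or `"samples_rows"`.
#' @param provenance tag stored on the result.
#' @return a [count_table] (samples x taxa).
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows"),
                             provenance = path) {
  orientation <- match.arg(orientation)
  df <- read_tsv_raw(path)
  abort_if(ncol(df) < 2, "count table needs an id column plus data columns")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at row '%s', column '%s' in %s",
                 ids[idx[1]], colnames(m)[idx[2]], path), call. = FALSE)
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    idx <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row '%s', column '%s' in %s",
                 ids[idx[1]], colnames(m)[idx[2]], path), call. = FALSE)
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row '%s', column '%s' in %s",
                 ids[idx[1]], colnames(m)[idx[2]], path), call. = FALSE)
  }
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  count_table(m, provenance = provenance)
}

#' Write a count table to TSV
#'
#' @param t a [count_table].
#' @param path output path.
#' @param orientation layout on disk; see [read_count_table].
#' @param id_column header of the first column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(t, path,
                              orientation = c("taxa_rows", "samples_rows"),
                              id_column = NULL) {
  orientation <- match.arg(orientation)
  m <- unclass(t)
  if (orientation == "taxa_rows") {
    m <- t(m)
    if (is.null(id_column)) id_column <- "otu_id"
  } else if (is.null(id_column)) id_column <- "sample_id"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a 7-rank taxonomy map from TSV
#'
#' Expects a `taxon_id` column plus rank columns (domain..species); extra
#' columns are ignored and missing trailing ranks are filled empty.
#'
#' @param path TSV file.
#' @return a [taxonomy_map].
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_raw(path)
  names(df) <- tolower(names(df))
  taxonomy_map(df)
}

#' Write a taxonomy map to TSV
#' @param tax a [taxonomy_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(as.data.frame(tax), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Missing values are encoded `NA`. Analyses needing a variable drop samples
#' that lack it for that variable only.
#'
#' @param path TSV file with `sample_id`, `cave`, `niche` and factor columns.
#' @return a [sample_metadata].
#' @export
read_sample_metadata <- function(path) sample_metadata(read_tsv_raw(path))

#' Write sample metadata to TSV
#' @param meta a [sample_metadata].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted Newick tree over taxa
#'
#' @param path Newick file with branch lengths.
#' @param taxon_ids optional character vector; if given, tips not covering all
#'   of `taxon_ids` trigger a warning listing the missing taxa.
#' @return an ape `phylo`, validated (unique tips, finite non-negative branch
#'   lengths).
#' @export
read_newick <- function(path, taxon_ids = NULL) {
  abort_if(!file.exists(path), "file not found: %s", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop(sprintf(
                     "failed to parse Newick file %s: %s", path,
                     conditionMessage(e)), call. = FALSE))
  abort_if(is.null(tree), "failed to parse Newick file %s", path)
  tree <- validate_tree(tree)
  if (!is.null(taxon_ids)) {
    miss <- setdiff(taxon_ids, tree$tip.label)
    if (length(miss) > 0)
      warning(sprintf("tree is missing %d taxa: %s", length(miss),
                      paste(utils::head(miss, 10), collapse = ", ")),
              call. = FALSE)
  }
  tree
}

#' Write a tree to Newick
#' @param tree an ape `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Serialize a co-occurrence network
#'
#' Writes GraphML (node attributes: genus label, phylum, module, betweenness;
#' edge attribute rho) plus a flat edge list CSV with columns
#' `source,target,rho,p,q`.
#'
#' @param net a `coocc_network` (see [build_network]).
#' @param graphml_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_network <- function(net, graphml_path = NULL, csv_path = NULL) {
  stopifnot(inherits(net, "coocc_network"))
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(csv_path)) {
    ed <- net$edges
    if (nrow(ed) == 0)
      ed <- data.frame(source = character(), target = character(),
                       rho = numeric(), p = numeric(), q = numeric())
    utils::write.table(ed, csv_path, sep = ",", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(graphml = graphml_path, csv = csv_path))
}

#' Read a network edge list CSV back into an igraph graph
#'
#' Round-trip companion of [write_network]; reconstructs the adjacency (and
#' edge weights rho) from the `source,target,rho,p,q` CSV.
#'
#' @param csv_path edge list written by [write_network].
#' @return an undirected igraph graph with edge attributes `rho`, `p`, `q`.
#' @export
read_network_csv <- function(csv_path) {
  abort_if(!file.exists(csv_path), "file not found: %s", csv_path)
  ed <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (nrow(ed) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  g
}
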