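## Genus co-occurrence networks: taxon selection, Spearman correlation,
## thresholded graph construction, topology, keystones, module-niche
## preference.

#' Select genera abundant enough for network construction
#'
#' Keeps a genus iff its mean relative abundance strictly exceeds
#' `threshold` (default 0.05%) within the requested scope: the whole dataset
#' (`scope = "overall"`) or the samples of one niche.
#'
#' @param rel a relative [abundance_table] (genus level, samples in rows).
#' @param meta a [sample_metadata]; required for niche scopes.
#' @param scope `"overall"` or one of [CAVE_NICHES].
#' @param threshold strict lower bound on mean relative abundance, in (0, 1).
#' @return character vector of retained genus labels.
#' @export
select_network_taxa <- function(rel, meta = NULL, scope = "overall",
                                threshold = 0.0005) {
  abort_if(threshold <= 0 || threshold >= 1, "threshold must be in (0,1)")
  m <- unclass(as.matrix(rel))
  if (scope != "overall") {
    abort_if(!scope %in% CAVE_NICHES, "unknown scope '%s'", scope)
    abort_if(is.null(meta), "niche scope requires sample metadata")
    meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
    m <- m[meta$niche == scope, , drop = FALSE]
    abort_if(nrow(m) == 0, "no samples in niche '%s'", scope)
  }
  colnames(m)[colMeans(m) > threshold]
}

#' All-pairs Spearman correlation matrix with p-values
#'
#' Midrank Spearman rho for every genus pair, with the two-sided t
#' approximation for p. Constant genera yield `NA` rho/p for their pairs
#' (and are never eligible for edges).
#'
#' @param t abundance matrix, samples in rows (>= 4 samples).
#' @param taxa optional subset of column names to correlate.
#' @return list with matrices `rho` and `p` (diagonal 1 and 0).
#' @export
correlation_matrix <- function(t, taxa = NULL) {
  m <- unclass(as.matrix(t))
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, colnames(m))
    abort_if(length(miss) > 0, "taxa not in table: %s",
             paste(utils::head(miss, 5), collapse = ", "))
    m <- m[, taxa, drop = FALSE]
  }
  n <- nrow(m)
  abort_if(n < 4, "need at least 4 samples for correlations")
  R <- apply(m, 2L, rank)
  constant <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(stats::cor(R))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  diag(rho) <- 1
  diag(p) <- 0
  list(rho = rho, p = p)
}

#' Build a co-occurrence network from correlation matrices
#'
#' An edge joins genera u, v iff `rho(u,v) > rho_min` (or `|rho| > rho_min`
#' with `absolute = TRUE`) and the (BH-adjusted, when `fdr = TRUE`) p-value
#' is below `p_max`. Adjustment is across all tested pairs. Genera left
#' without any edge are dropped from the graph.
#'
#' @param rho,p square matrices from [correlation_matrix].
#' @param rho_min correlation threshold (default 0.6, strict).
#' @param p_max significance threshold on the (adjusted) p (default 0.01).
#' @param fdr adjust pair p-values by Benjamini-Hochberg (default `TRUE`).
#' @param absolute admit strong negative correlations too (default `FALSE`:
#'   co-occurrence only).
#' @param node_data optional data.frame with a `label` column plus node
#'   attributes (e.g. `phylum`) copied onto graph vertices.
#' @return list of class `coocc_network`: `graph` (igraph), `edges`
#'   (data.frame `source,target,rho,p,q`), `nodes` (labels in the graph).
#' @export
build_network <- function(rho, p, rho_min = 0.6, p_max = 0.01, fdr = TRUE,
                          absolute = FALSE, node_data = NULL) {
  stopifnot(identical(dim(rho), dim(p)), nrow(rho) == ncol(rho))
  labs <- colnames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  pr_rho <- rho[ut]
  pr_p <- p[ut]
  tested <- !is.na(pr_p)
  q <- rep(NA_real_, length(pr_p))
  q[tested] <- if (fdr) stats::p.adjust(pr_p[tested], method = "BH")
               else pr_p[tested]
  strength <- if (absolute) abs(pr_rho) else pr_rho
  sel <- tested & strength > rho_min & q < p_max
  edges <- data.frame(source = labs[ut[sel, 1]], target = labs[ut[sel, 2]],
                      rho = pr_rho[sel], p = pr_p[sel], q = q[sel],
                      stringsAsFactors = FALSE)
  g <- if (nrow(edges) > 0) {
    igraph::graph_from_data_frame(edges, directed = FALSE)
  } else igraph::make_empty_graph(0, directed = FALSE)
  if (!is.null(node_data) && igraph::vcount(g) > 0) {
    stopifnot("label" %in% names(node_data))
    idx <- match(igraph::V(g)$name, node_data$label)
    for (col in setdiff(names(node_data), "label")) {
      vals <- node_data[[col]][idx]
      g <- igraph::set_vertex_attr(g, col, value = vals)
    }
  }
  structure(list(graph = g, edges = edges,
                 nodes = if (igraph::vcount(g) > 0) igraph::V(g)$name
                         else character()),
            class = "coocc_network")
}

#' @export
print.coocc_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' One-call network construction from a genus table
#'
#' Convenience wrapper: relative abundance, scope-specific genus selection,
#' Spearman correlation on the scope's samples, thresholded graph.
#'
#' @param genus_table genus-level [count_table] or [abundance_table].
#' @param meta a [sample_metadata].
#' @param scope `"overall"` or a niche; correlations use only the scope's
#'   samples.
#' @param taxonomy optional [taxonomy_map] (genus-level) to attach phylum to
#'   nodes.
#' @param abundance_threshold,rho_min,p_max,fdr,absolute see
#'   [select_network_taxa] and [build_network].
#' @return a `coocc_network`.
#' @export
cooccurrence_network <- function(genus_table, meta, scope = "overall",
                                 taxonomy = NULL,
                                 abundance_threshold = 0.0005,
                                 rho_min = 0.6, p_max = 0.01, fdr = TRUE,
                                 absolute = FALSE) {
  rel <- to_relative(genus_table)
  keep <- select_network_taxa(rel, meta, scope = scope,
                              threshold = abundance_threshold)
  abort_if(length(keep) < 2, "fewer than 2 genera pass the %s filter", scope)
  m <- unclass(rel)
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  if (scope != "overall") m <- m[meta$niche == scope, , drop = FALSE]
  cm <- correlation_matrix(m, taxa = keep)
  node_data <- NULL
  if (!is.null(taxonomy)) {
    idx <- match(keep, taxonomy$taxon_id)
    node_data <- data.frame(label = keep, phylum = taxonomy$phylum[idx],
                            stringsAsFactors = FALSE)
  }
  build_network(cm$rho, cm$p, rho_min = rho_min, p_max = p_max, fdr = fdr,
                absolute = absolute, node_data = node_data)
}

#' Topology metrics of a co-occurrence network
#'
#' Degree, average degree (AD), clustering coefficient (CC: mean of local
#' clustering coefficients, nodes of degree < 2 contributing 0; global
#' transitivity also reported), average path length (APL) and diameter (ND)
#' over all connected pairs (giant-component variants reported alongside),
#' Brandes betweenness centrality (undirected, unnormalized), and Louvain
#' modules (resolution 1, best modularity of `restarts` node-order shuffles,
#' deterministic under `seed`).
#'
#' @param net a `coocc_network` or an igraph graph with >= 1 edge.
#' @param seed integer seed for the Louvain restarts.
#' @param restarts Louvain restarts (default 10).
#' @return list of class `network_topology`: `n_nodes`, `n_edges`,
#'   `average_degree`, `clustering_coefficient`, `transitivity_global`,
#'   `average_path_length`, `diameter`, `apl_giant`, `diameter_giant`,
#'   `modularity`, `n_modules`, and `nodes` (per-node data.frame with
#'   `node`, `degree`, `betweenness`, `module`).
#' @export
topology <- function(net, seed = 1L, restarts = 10L) {
  g <- if (inherits(net, "coocc_network")) net$graph else net
  abort_if(igraph::ecount(g) == 0, "topology undefined for an empty network")
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc_local[!is.finite(cc_local)] <- 0
  D <- igraph::distances(g)
  finite <- D[upper.tri(D)][is.finite(D[upper.tri(D)])]
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  Dg <- igraph::distances(giant)
  fg <- Dg[upper.tri(Dg)]
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, resolution = 1)
      memb <- igraph::membership(cl)[match(igraph::V(g)$name,
                                           igraph::V(gp)$name)]
      q <- igraph::modularity(g, memb)
      if (is.null(best) || q > best$q + 1e-12) best <- list(q = q, memb = memb)
    }
  })
  modules <- as.integer(best$memb)

  structure(list(
    n_nodes = n, n_edges = e,
    average_degree = 2 * e / n,
    clustering_coefficient = mean(cc_local),
    transitivity_global = igraph::transitivity(g, type = "global"),
    average_path_length = if (length(finite) > 0) mean(finite) else NA_real_,
    diameter = if (length(finite) > 0) max(finite) else NA_real_,
    apl_giant = mean(fg), diameter_giant = max(fg),
    modularity = best$q, n_modules = length(unique(modules)),
    nodes = data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
                       betweenness = bc, module = modules,
                       row.names = NULL, stringsAsFactors = FALSE)),
    class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(paste0("network topology: %d nodes, %d edges | AD %.3f, ",
                     "CC %.3f, APL %.3f, ND %g, MD %.3f (%d modules)\n"),
              x$n_nodes, x$n_edges, x$average_degree,
              x$clustering_coefficient, x$average_path_length, x$diameter,
              x$modularity, x$n_modules))
  invisible(x)
}

#' Rank keystone genera by betweenness centrality
#'
#' Nodes sorted by betweenness descending, ties broken by degree descending
#' then label ascending; the top `k` are the keystone candidates.
#'
#' @param topo a `network_topology`.
#' @param k number of keystones (default 3); truncated with a warning if the
#'   network is smaller.
#' @return data.frame: `rank`, `node`, `betweenness`, `degree`, `module`.
#' @export
keystones <- function(topo, k = 3) {
  stopifnot(inherits(topo, "network_topology"))
  nd <- topo$nodes
  ord <- order(-nd$betweenness, -nd$degree, nd$node)
  if (k > nrow(nd)) {
    warning(sprintf("k = %d exceeds network size %d; truncating", k,
                    nrow(nd)), call. = FALSE)
    k <- nrow(nd)
  }
  top <- nd[ord[seq_len(k)], c("node", "betweenness", "degree", "module")]
  data.frame(rank = seq_len(k), top, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Niche preference of network modules
#'
#' Each node's preferred niche is the niche where its mean relative
#' abundance is highest (ties broken by the fixed niche order). Per module,
#' counts of nodes per preferred niche and the majority niche.
#'
#' @param topo a `network_topology`.
#' @param genus_table genus-level counts or abundances over all samples.
#' @param meta a [sample_metadata].
#' @return list with `nodes` (node, module, preferred_niche) and `modules`
#'   (module, size, majority_niche, plus one count column per niche).
#' @export
module_niche_preference <- function(topo, genus_table, meta) {
  stopifnot(inherits(topo, "network_topology"))
  rel <- unclass(to_relative(genus_table))
  meta <- meta[match(rownames(rel), meta$sample_id), , drop = FALSE]
  miss <- setdiff(topo$nodes$node, colnames(rel))
  abort_if(length(miss) > 0, "nodes missing abundance profiles: %s",
           paste(utils::head(miss, 5), collapse = ", "))
  niche_mean <- vapply(CAVE_NICHES, function(nch)
    colMeans(rel[meta$niche == nch, topo$nodes$node, drop = FALSE]),
    numeric(nrow(topo$nodes)))
  if (nrow(topo$nodes) == 1L) niche_mean <- matrix(niche_mean, nrow = 1,
      dimnames = list(topo$nodes$node, CAVE_NICHES))
  pref <- CAVE_NICHES[max.col(niche_mean, ties.method = "first")]
  nodes <- data.frame(node = topo$nodes$node, module = topo$nodes$module,
                      preferred_niche = pref, stringsAsFactors = FALSE)
  mods <- sort(unique(nodes$module))
  tab <- t(vapply(mods, function(mm)
    as.integer(table(factor(nodes$preferred_niche[nodes$module == mm],
                            levels = CAVE_NICHES))), integer(4)))
  colnames(tab) <- CAVE_NICHES
  modules <- data.frame(module = mods, size = as.integer(rowSums(tab)),
                        majority_niche = CAVE_NICHES[max.col(tab,
                                                    ties.method = "first")],
                        tab, row.names = NULL, stringsAsFactors = FALSE)
  list(nodes = nodes, modules = modules)
}
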