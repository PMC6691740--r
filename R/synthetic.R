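## Synthetic cave-community generator.
##
## Latent log-abundance model per sample s (niche n, cave c) and taxon t:
##   z_t(s) = mu_t + delta * 1[t indicator of n]
##          + eta   * 1[t in block with preferred niche n]
##          + gamma_{t,c} + sum_f beta_{t,f} (x_f(s) - xbar_f) + u_t(s)
## u(s) is multivariate normal with a block factor structure: members of
## correlation block b load sqrt(block_rho) on factor f_b; the hub taxon IS a
## latent factor g, and the factors of the `hub_links` hub-linked blocks are
## coupled to g with weight sqrt(hub_coupling). Hence latent correlations:
##   member-member within block:     block_rho
##   hub-member (linked blocks):     sqrt(block_rho * hub_coupling)
##   member-member across linked:    block_rho * hub_coupling
## Relative abundances are softmax(z); counts are multinomial(depth, p).

#' Specification of a synthetic cave community
#'
#' Defaults emulate the survey design the pipeline targets: 8 caves x 4
#' niches x 4 samples = 128 samples, 600 taxa, 30,000 reads/sample, 5 planted
#' indicator taxa per niche with a log-scale effect of 2, four planted
#' correlation blocks of 12 taxa at within-block latent correlation 0.7 (each
#' block preferentially abundant in one niche), and one hub taxon coupled to
#' two blocks.
#'
#' @param n_caves number of caves.
#' @param samples_per_cave_per_niche replicates per cave x niche cell.
#' @param n_taxa number of taxa (OTUs).
#' @param depth sequencing reads per sample.
#' @param n_indicators_per_niche planted indicator taxa per niche.
#' @param indicator_effect log-scale abundance shift of an indicator in its
#'   target niche.
#' @param n_blocks,block_size,block_rho planted correlation blocks: count,
#'   taxa per block, within-block latent correlation in `[0, 1)`.
#' @param block_niche_effect log-scale shift of block members in the block's
#'   preferred niche (blocks are assigned niches cyclically).
#' @param hub_links number of blocks the planted hub taxon couples to.
#' @param hub_coupling squared loading of a hub-linked block's factor on the
#'   hub; hub-member latent correlation is `sqrt(block_rho * hub_coupling)`.
#' @param covariate_effects named numeric vector of per-unit log-abundance
#'   slopes for environmental factors (names among `temperature`, `depth_m`,
#'   `air_humidity`); each factor affects `n_gradient_taxa` designated taxa.
#' @param n_gradient_taxa taxa affected by each covariate.
#' @param cave_sd sd of per-cave random effects.
#' @param noise_sd sd of the latent residual `u`.
#' @param mu_sd sd of baseline log-abundances (controls rank-abundance skew).
#' @param planted_mu_mean,planted_mu_sd baseline log-abundance distribution
#'   of planted structural taxa (indicators, block members, hub, gradient
#'   taxa). Defaults place them one background-sd above the community mean:
#'   co-occurrence analysis applies only to the abundant core (genera above
#'   the 0.05% filter), so structure is planted where the method can see it.
#' @param seed integer seed; the whole dataset is deterministic given it.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_caves = 8L,
                           samples_per_cave_per_niche = 4L,
                           n_taxa = 600L,
                           depth = 30000L,
                           n_indicators_per_niche = 5L,
                           indicator_effect = 2.0,
                           n_blocks = 4L,
                           block_size = 12L,
                           block_rho = 0.7,
                           block_niche_effect = 0.5,
                           hub_links = 2L,
                           hub_coupling = 0.7,
                           covariate_effects = c(temperature = 0.05),
                           n_gradient_taxa = 20L,
                           cave_sd = 0.25,
                           noise_sd = 1.0,
                           mu_sd = 1.5,
                           planted_mu_mean = 1.5,
                           planted_mu_sd = 0.5,
                           seed = 1L) {
  spec <- list(n_caves = as.integer(n_caves),
               niches = CAVE_NICHES,
               samples_per_cave_per_niche = as.integer(samples_per_cave_per_niche),
               n_taxa = as.integer(n_taxa), depth = as.integer(depth),
               n_indicators_per_niche = as.integer(n_indicators_per_niche),
               indicator_effect = indicator_effect,
               n_blocks = as.integer(n_blocks),
               block_size = as.integer(block_size),
               block_rho = block_rho,
               block_niche_effect = block_niche_effect,
               hub_links = as.integer(hub_links),
               hub_coupling = hub_coupling,
               covariate_effects = covariate_effects,
               n_gradient_taxa = as.integer(n_gradient_taxa),
               cave_sd = cave_sd, noise_sd = noise_sd, mu_sd = mu_sd,
               planted_mu_mean = planted_mu_mean,
               planted_mu_sd = planted_mu_sd,
               seed = as.integer(seed))
  abort_if(spec$depth < 1, "depth must be >= 1")
  abort_if(spec$block_rho < 0 || spec$block_rho >= 1,
           "block_rho must be in [0, 1)")
  abort_if(spec$hub_coupling < 0 || spec$hub_coupling > 1,
           "hub_coupling must be in [0, 1]")
  abort_if(spec$hub_links > spec$n_blocks, "hub_links exceeds n_blocks")
  n_planted <- 4L * spec$n_indicators_per_niche +
    spec$n_blocks * spec$block_size + 1L +
    length(spec$covariate_effects) * spec$n_gradient_taxa
  abort_if(spec$n_blocks * spec$block_size > spec$n_taxa,
           "block_size x n_blocks exceeds n_taxa")
  abort_if(n_planted > spec$n_taxa,
           "planted structure needs %d taxa but n_taxa = %d",
           n_planted, spec$n_taxa)
  class(spec) <- "synthetic_spec"
  spec
}

## Disjoint planted-taxon index layout, in taxon order:
## indicators (4 * k), block members (n_blocks * block_size), hub (1),
## gradient taxa (per covariate), then free background taxa.
plant_layout <- function(spec) {
  idx <- 0L
  take <- function(n) {
    out <- seq_len(n) + idx
    idx <<- idx + n
    out
  }
  ind <- take(4L * spec$n_indicators_per_niche)
  blocks <- lapply(seq_len(spec$n_blocks), function(b) take(spec$block_size))
  hub <- take(1L)
  grad <- lapply(seq_along(spec$covariate_effects),
                 function(f) take(spec$n_gradient_taxa))
  names(grad) <- names(spec$covariate_effects)
  list(indicators = ind, blocks = blocks, hub = hub, gradient = grad)
}

generate_metadata <- function(spec) {
  caves <- sprintf("cave%02d", seq_len(spec$n_caves))
  grid <- expand.grid(rep = seq_len(spec$samples_per_cave_per_niche),
                      niche = spec$niches, cave = caves,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  # cave-level environmental means follow the ranges reported for karst
  # caves: temperature 11-25 C, humidity 80-91 %, pH 7.9-8.3
  cave_temp <- stats::runif(spec$n_caves, 11, 25)
  cave_hum <- stats::runif(spec$n_caves, 80, 91)
  cave_ph <- stats::runif(spec$n_caves, 7.9, 8.3)
  ci <- match(grid$cave, caves)
  temp <- cave_temp[ci] + stats::rnorm(n, 0, 0.7)
  hum <- pmin(100, pmax(60, cave_hum[ci] + stats::rnorm(n, 0, 2)))
  ph <- cave_ph[ci] + stats::rnorm(n, 0, 0.3)
  depth_m <- stats::runif(n, 10, 300)
  toc <- exp(stats::rnorm(n, 1.0, 0.7))          # g/kg, log-normal
  tn <- toc / 10 * exp(stats::rnorm(n, 0, 0.3))  # tracks TOC with noise
  moist <- pmin(60, pmax(2, stats::rnorm(n, 25, 8)))  # % dry weight
  substrate <- grid$niche %in% c("water", "rock", "sediment")
  sample_metadata(data.frame(
    sample_id = sprintf("%s_%s_%d", grid$cave, grid$niche, grid$rep),
    cave = grid$cave, niche = grid$niche,
    depth_m = round(depth_m, 1),
    temperature = round(temp, 2),
    air_humidity = round(hum, 1),
    pH = ifelse(substrate, round(ph, 2), NA_real_),
    TOC = ifelse(substrate, round(toc, 3), NA_real_),
    TN = ifelse(substrate, round(tn, 4), NA_real_),
    moisture = ifelse(grid$niche == "sediment", round(moist, 1), NA_real_),
    stringsAsFactors = FALSE))
}

generate_taxonomy <- function(spec, layout) {
  n <- spec$n_taxa
  taxa <- sprintf("OTU_%04d", seq_len(n))
  phyla <- sprintf("Phylum%02d", 1:12)
  # skewed phylum probabilities: a few dominant phyla as in real surveys
  pw <- exp(-0.45 * (0:11)); pw <- pw / sum(pw)
  phy <- sample(phyla, n, replace = TRUE, prob = pw)
  genus <- character(n)
  family <- sprintf("Family%03d", 1 + (seq_len(n) - 1L) %/% 4L)
  planted <- sort(unique(c(layout$indicators, unlist(layout$blocks),
                           layout$hub, unlist(layout$gradient))))
  # planted taxa get singleton genera so genus aggregation preserves truth
  genus[planted] <- sprintf("Genus_p%03d", seq_along(planted))
  bg <- setdiff(seq_len(n), planted)
  pool <- sprintf("Genus_b%03d", seq_len(max(1L, length(bg) %/% 3L)))
  genus[bg] <- sample(pool, length(bg), replace = TRUE)
  # ~5% of background taxa unassigned at genus: exercises the
  # "<family>__unclassified" aggregation path
  uncl <- sample(bg, max(1L, round(0.05 * length(bg))))
  genus[uncl] <- ""
  df <- data.frame(taxon_id = taxa, domain = "Bacteria", phylum = phy,
                   class = paste0(phy, "_c"), order = paste0(phy, "_o"),
                   family = family, genus = genus,
                   species = "", stringsAsFactors = FALSE)
  taxonomy_map(df)
}

#' Generate a synthetic cave community dataset with known ground truth
#'
#' @param spec a [synthetic_spec].
#' @return a list with elements `counts` ([count_table]), `taxonomy`
#'   ([taxonomy_map]), `metadata` ([sample_metadata]), `tree` (ape `phylo`),
#'   and `truth` (planted indicator assignments, block memberships and
#'   niches, hub taxon, gradient taxa, and the generating [synthetic_spec]).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    layout <- plant_layout(spec)
    meta <- generate_metadata(spec)
    tax <- generate_taxonomy(spec, layout)
    n_s <- nrow(meta)
    n_t <- spec$n_taxa
    taxa <- tax$taxon_id

    mu <- stats::rnorm(n_t, 0, spec$mu_sd)
    planted <- sort(unique(c(layout$indicators, unlist(layout$blocks),
                             layout$hub, unlist(layout$gradient))))
    mu[planted] <- stats::rnorm(length(planted), spec$planted_mu_mean,
                                spec$planted_mu_sd)
    Z <- matrix(mu, n_s, n_t, byrow = TRUE)

    # planted indicators: n_indicators_per_niche per niche, in niche order
    ind_niche <- rep(spec$niches, each = spec$n_indicators_per_niche)
    for (i in seq_along(layout$indicators)) {
      t_i <- layout$indicators[i]
      Z[meta$niche == ind_niche[i], t_i] <-
        Z[meta$niche == ind_niche[i], t_i] + spec$indicator_effect
    }

    # blocks: cyclic niche preference (block b -> niche ((b-1) mod 4) + 1)
    block_niche <- spec$niches[((seq_len(spec$n_blocks) - 1L) %% 4L) + 1L]
    for (b in seq_len(spec$n_blocks)) {
      mem <- layout$blocks[[b]]
      sel <- meta$niche == block_niche[b]
      Z[sel, mem] <- Z[sel, mem] + spec$block_niche_effect
    }

    # cave random effects
    if (spec$cave_sd > 0) {
      caves <- unique(meta$cave)
      gam <- matrix(stats::rnorm(n_t * length(caves), 0, spec$cave_sd),
                    length(caves), n_t)
      Z <- Z + gam[match(meta$cave, caves), , drop = FALSE]
    }

    # environmental gradients on designated taxa (centered covariates)
    for (f in names(spec$covariate_effects)) {
      beta <- spec$covariate_effects[[f]]
      if (beta == 0) next
      x <- meta[[f]]
      x <- x - mean(x, na.rm = TRUE)
      x[is.na(x)] <- 0
      mem <- layout$gradient[[f]]
      Z[, mem] <- Z[, mem] + outer(x, rep(beta, length(mem)))
    }

    # residual u with block factor structure. Shared factors are centered
    # within niche groups: otherwise their random niche-means add an
    # uncontrolled niche preference to whole blocks, contradicting the
    # planted block-niche truth labels.
    center_by_niche <- function(v) v - stats::ave(v, meta$niche)
    U <- matrix(stats::rnorm(n_s * n_t), n_s, n_t)
    g <- center_by_niche(stats::rnorm(n_s))      # hub factor
    for (b in seq_len(spec$n_blocks)) {
      fb <- center_by_niche(stats::rnorm(n_s))
      if (b <= spec$hub_links && spec$hub_coupling > 0)
        fb <- sqrt(spec$hub_coupling) * g + sqrt(1 - spec$hub_coupling) * fb
      mem <- layout$blocks[[b]]
      if (spec$block_rho > 0)
        U[, mem] <- sqrt(spec$block_rho) * fb +
          sqrt(1 - spec$block_rho) * U[, mem]
    }
    U[, layout$hub] <- g
    Z <- Z + spec$noise_sd * U

    # softmax rows -> multinomial counts
    P <- exp(Z - apply(Z, 1L, max))
    P <- P / rowSums(P)
    counts <- t(vapply(seq_len(n_s),
                       function(i) stats::rmultinom(1L, spec$depth, P[i, ])[, 1],
                       integer(n_t)))
    dimnames(counts) <- list(meta$sample_id, taxa)
    ct <- count_table(counts, provenance = sprintf("synthetic(seed=%d)",
                                                   spec$seed))

    tree <- generate_tree(taxa, seed = child_seed(spec$seed, "tree"))

    truth <- list(
      indicators = data.frame(taxon_id = taxa[layout$indicators],
                              niche = ind_niche, stringsAsFactors = FALSE),
      blocks = data.frame(
        taxon_id = taxa[unlist(layout$blocks)],
        block = rep(seq_len(spec$n_blocks), each = spec$block_size),
        niche = rep(block_niche, each = spec$block_size),
        stringsAsFactors = FALSE),
      hub = taxa[layout$hub],
      gradient = if (length(layout$gradient) > 0) data.frame(
        taxon_id = taxa[unlist(layout$gradient)],
        factor = rep(names(layout$gradient),
                     vapply(layout$gradient, length, 1L)),
        stringsAsFactors = FALSE) else NULL,
      spec = spec)

    list(counts = ct, taxonomy = tax, metadata = meta, tree = tree,
         truth = truth)
  })
}

#' Generate a random rooted binary tree over taxa
#'
#' Sequential random joins: repeatedly pick two subtrees uniformly at random
#' and join them under a new root; every branch length is exponential(1).
#'
#' @param taxon_ids character vector of tip labels (length >= 2).
#' @param seed integer seed.
#' @return an ape `phylo`, rooted and binary (n leaves, n - 1 internal nodes).
#' @export
generate_tree <- function(taxon_ids, seed = 1L) {
  abort_if(length(taxon_ids) < 2, "need at least 2 taxa for a tree")
  abort_if(anyDuplicated(taxon_ids) > 0, "duplicate taxon ids")
  with_seed(seed, {
    parts <- as.list(taxon_ids)
    while (length(parts) > 1L) {
      ij <- sample.int(length(parts), 2L)
      l <- stats::rexp(2L)
      joined <- sprintf("(%s:%.6f,%s:%.6f)", parts[[ij[1]]], l[1],
                        parts[[ij[2]]], l[2])
      parts[[ij[1]]] <- joined
      parts[[ij[2]]] <- NULL
    }
    tree <- ape::read.tree(text = paste0(parts[[1]], ";"))
    validate_tree(tree)
  })
}

#' Write a generated dataset to a directory
#'
#' Writes `counts.tsv` (taxa in rows), `taxonomy.tsv`, `metadata.tsv`,
#' `tree.nwk` and `truth.json`.
#'
#' @param dataset result of [generate_dataset].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             tree = file.path(dir, "tree.nwk"),
             truth = file.path(dir, "truth.json"))
  write_count_table(dataset$counts, paths[["counts"]],
                    orientation = "taxa_rows")
  write_taxonomy(dataset$taxonomy, paths[["taxonomy"]])
  write_sample_metadata(dataset$metadata, paths[["metadata"]])
  write_newick(dataset$tree, paths[["tree"]])
  tr <- dataset$truth
  tr$spec <- unclass(tr$spec)
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
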