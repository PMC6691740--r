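## End-to-end recovery experiment: repeatedly generate a synthetic community
## with planted ground truth, run the analysis stages that the truth speaks
## to, and score recovery. This is the analysis-level validation surface of
## the package.

#' Run the recovery experiment over replicate synthetic datasets
#'
#' For each of `n_seeds` replicates: generate a dataset from `spec_args`
#' (defaults = the stated synthetic world: 128 samples, 600 taxa, depth
#' 30,000, indicator effect 2.0, four blocks of 12 at latent correlation 0.7,
#' one hub coupled to two blocks), then run rare-OTU filtering, CSS
#' normalization, genus aggregation, genus-level IndVal (999 permutations),
#' Bray-Curtis + PERMANOVA on niche (999 permutations), and the overall
#' co-occurrence network with topology, keystones and module-niche
#' preference; finally score recovery against the planted truth with
#' [truth_recovery].
#'
#' @param n_seeds number of replicate datasets.
#' @param base_seed root seed; replicate r uses `child_seed(base_seed,
#'   "recovery<r>")`.
#' @param spec_args named list of [synthetic_spec] overrides.
#' @param n_perm permutations for IndVal and PERMANOVA (default 999).
#' @param keystone_k keystone list length (default 3).
#' @return data.frame with one row per seed: `seed`,
#'   `indicator_sensitivity`, `indicator_false_positive_rate`, `module_ari`,
#'   `hub_in_keystones`, `block_majority_niche_rate`, `permanova_niche_p`,
#'   `n_network_nodes`, `n_network_edges`.
#' @export
recovery_experiment <- function(n_seeds = 50, base_seed = 1,
                                spec_args = list(), n_perm = 999,
                                keystone_k = 3) {
  rows <- vector("list", n_seeds)
  for (r in seq_len(n_seeds)) {
    seed_r <- child_seed(base_seed, paste0("recovery", r))
    spec <- do.call(synthetic_spec, c(spec_args, list(seed = seed_r)))
    d <- generate_dataset(spec)
    filtered <- filter_rare_otus(d$counts)
    css <- css_normalize(filtered)
    meta <- align_metadata(filtered, d$metadata)

    genus <- aggregate_to_genus(filtered, d$taxonomy)
    iv <- indval(css_normalize(genus), meta$niche, n_perm = n_perm,
                 seed = child_seed(seed_r, "indval"))

    pm <- permanova(bray_curtis(css), meta$niche, n_perm = n_perm,
                    seed = child_seed(seed_r, "permanova"),
                    grouping = "niche")

    topo <- NULL; keys <- NULL; mnp <- NULL
    net <- tryCatch(
      cooccurrence_network(genus, meta, scope = "overall"),
      error = function(e) NULL)
    if (!is.null(net) && nrow(net$edges) > 0) {
      topo <- topology(net, seed = child_seed(seed_r, "louvain"))
      keys <- keystones(topo, k = keystone_k)
      mnp <- module_niche_preference(topo, genus, meta)
    }
    rec <- truth_recovery(d$truth, d$taxonomy, iv, topo = topo, keys = keys,
                          module_niche = mnp, permanova_p = pm$p_value)
    rows[[r]] <- data.frame(
      seed = seed_r,
      indicator_sensitivity = rec$indicator_sensitivity,
      indicator_false_positive_rate = rec$indicator_false_positive_rate,
      indicator_fpr_incl_blocks = rec$indicator_fpr_incl_blocks,
      module_ari = rec$module_ari,
      hub_in_keystones = rec$hub_in_keystones,
      block_majority_niche_rate = rec$block_majority_niche_rate,
      permanova_niche_p = rec$permanova_niche_p,
      n_network_nodes = if (is.null(topo)) 0L else topo$n_nodes,
      n_network_edges = if (is.null(topo)) 0L else topo$n_edges)
  }
  do.call(rbind, rows)
}
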