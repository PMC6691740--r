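test_that("the abundance filter is strict and matches brute force", {
  rel <- abundance_table(rbind(
    s1 = c(g1 = 0.0004, g2 = 0.0005, g3 = 0.0006, g4 = 0.9985),
    s2 = c(g1 = 0.0004, g2 = 0.0005, g3 = 0.0006, g4 = 0.9985)),
    method = "relative")
  keep <- select_network_taxa(rel, threshold = 0.0005)
  expect_identical(keep, c("g3", "g4"))      # 0.04% out, exactly 0.05% out
  expect_error(select_network_taxa(rel, threshold = 0), "in \\(0,1\\)")

  withr::with_seed(41, {
    m <- matrix(stats::rexp(8 * 6), 8, 6,
                dimnames = list(paste0("s", 1:8), paste0("g", 1:6)))
    m <- m / rowSums(m)
    thr <- 0.1
    brute <- colnames(m)[vapply(seq_len(6), function(j)
      mean(m[, j]) > thr, NA)]
    expect_identical(select_network_taxa(abundance_table(m, "relative"),
                                         threshold = thr), brute)
  })
})

test_that("niche-scoped selection uses only that niche's samples", {
  rel <- abundance_table(rbind(
    a1 = c(g1 = 0.9, g2 = 0.1),
    a2 = c(g1 = 0.9, g2 = 0.1),
    w1 = c(g1 = 0.1, g2 = 0.9),
    w2 = c(g1 = 0.1, g2 = 0.9)), method = "relative")
  meta <- sample_metadata(data.frame(
    sample_id = c("a1", "a2", "w1", "w2"), cave = "c",
    niche = c("air", "air", "water", "water")))
  expect_identical(select_network_taxa(rel, meta, scope = "air",
                                       threshold = 0.5), "g1")
  expect_identical(select_network_taxa(rel, meta, scope = "water",
                                       threshold = 0.5), "g2")
})

test_that("the correlation matrix equals the per-pair midrank oracle", {
  withr::with_seed(43, {
    m <- matrix(stats::rnorm(10 * 20), 10, 20,
                dimnames = list(paste0("s", 1:10), paste0("g", 1:20)))
    cm <- correlation_matrix(m)
    for (pair in list(c(1, 2), c(3, 17), c(9, 20))) {
      i <- pair[1]; j <- pair[2]
      rho <- stats::cor(rank(m[, i]), rank(m[, j]))
      expect_equal(cm$rho[i, j], rho, tolerance = 1e-12)
      tt <- rho * sqrt(8 / (1 - rho^2))
      expect_equal(cm$p[i, j], 2 * stats::pt(-abs(tt), 8), tolerance = 1e-12)
    }
    expect_equal(diag(cm$rho), rep(1, 20), ignore_attr = TRUE)
    expect_equal(diag(cm$p), rep(0, 20), ignore_attr = TRUE)
    # anti-monotone pair
    m2 <- cbind(x = 1:6 + 0.0, y = -(1:6) + 0.0)
    rownames(m2) <- paste0("s", 1:6)
    expect_equal(correlation_matrix(m2)$rho["x", "y"], -1)
    # constant genus gives NA and no edges
    m3 <- cbind(m, const = rep(2, 10))
    cm3 <- correlation_matrix(m3)
    expect_true(all(is.na(cm3$rho["const", colnames(m)])))
  })
})

test_that("edge thresholds follow the rho > 0.6, adjusted p < 0.01 rule", {
  labs <- c("u", "v", "w")
  mk <- function(r, pv) {
    rho <- diag(3); p <- matrix(0, 3, 3)
    rho[1, 2] <- rho[2, 1] <- r
    p[1, 2] <- p[2, 1] <- pv
    rho[1, 3] <- rho[3, 1] <- 0; p[1, 3] <- p[3, 1] <- 0.9
    rho[2, 3] <- rho[3, 2] <- 0; p[2, 3] <- p[3, 2] <- 0.9
    dimnames(rho) <- dimnames(p) <- list(labs, labs)
    list(rho = rho, p = p)
  }
  x <- mk(0.61, 0.005)
  expect_identical(nrow(build_network(x$rho, x$p, fdr = FALSE)$edges), 1L)
  x <- mk(0.7, 0.02)
  expect_identical(nrow(build_network(x$rho, x$p, fdr = FALSE)$edges), 0L)
  x <- mk(-0.8, 0.001)
  expect_identical(nrow(build_network(x$rho, x$p, fdr = FALSE)$edges), 0L)
  expect_identical(nrow(build_network(x$rho, x$p, fdr = FALSE,
                                      absolute = TRUE)$edges), 1L)
  # BH adjustment across pairs is applied when fdr = TRUE
  x <- mk(0.61, 0.005)
  q_brute <- stats::p.adjust(c(0.005, 0.9, 0.9), method = "BH")[1]
  net <- build_network(x$rho, x$p, fdr = TRUE)
  if (q_brute < 0.01) expect_identical(nrow(net$edges), 1L) else
    expect_identical(nrow(net$edges), 0L)
})

test_that("topology metrics match hand computations on canonical graphs", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  t3 <- topology(k3, seed = 1)
  expect_equal(t3$clustering_coefficient, 1)
  expect_equal(t3$average_path_length, 1)
  expect_equal(t3$diameter, 1)
  expect_equal(t3$average_degree, 2)
  expect_true(all(t3$nodes$betweenness == 0))

  p3 <- igraph::make_graph(~ A - B, B - C)
  tp <- topology(p3, seed = 1)
  expect_equal(tp$nodes$betweenness[tp$nodes$node == "B"], 1)
  expect_equal(tp$average_path_length, 4 / 3)
  expect_equal(tp$diameter, 2)

  # two disjoint triangles: natural partition has Q = 0.5,
  # and Louvain finds it
  g2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                               igraph::make_full_graph(3))
  igraph::V(g2)$name <- paste0("n", 1:6)
  A <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
  expect_equal(modularity_brute(A, rep(1:2, each = 3)), 0.5)
  t2 <- topology(g2, seed = 3)
  expect_equal(t2$modularity, 0.5)
  expect_identical(t2$n_modules, 2L)
  # single-community partition has Q = 0
  expect_equal(modularity_brute(A, rep(1, 6)), 0)
  expect_equal(igraph::modularity(g2, rep(1, 6)), 0)
})

test_that("Louvain modularity equals direct evaluation of Q on its partition", {
  withr::with_seed(47, {
    for (i in 1:5) {
      rg <- random_connected_graph(12, p = 0.3)
      topo <- topology(rg$graph, seed = i)
      memb <- topo$nodes$module[match(igraph::V(rg$graph)$name,
                                      topo$nodes$node)]
      expect_equal(topo$modularity, modularity_brute(rg$A, memb),
                   tolerance = 1e-12)
    }
  })
})

test_that("betweenness equals the brute-force enumeration oracle", {
  withr::with_seed(53, {
    for (i in 1:12) {
      n <- sample(4:7, 1)
      rg <- random_connected_graph(n, p = 0.5)
      topo <- topology(rg$graph, seed = 1)
      brute <- betweenness_brute(rg$A)
      got <- topo$nodes$betweenness[match(igraph::V(rg$graph)$name,
                                          topo$nodes$node)]
      expect_equal(got, brute, tolerance = 1e-10)
    }
  })
})

test_that("APL and diameter equal Floyd-Warshall values on random graphs", {
  withr::with_seed(59, {
    for (i in 1:5) {
      rg <- random_connected_graph(sample(10:30, 1), p = 0.15)
      topo <- topology(rg$graph, seed = 1)
      D <- floyd_warshall(rg$A)
      ut <- D[upper.tri(D)]
      expect_equal(topo$average_path_length, mean(ut[is.finite(ut)]))
      expect_equal(topo$diameter, max(ut[is.finite(ut)]))
    }
  })
})

test_that("keystones rank by betweenness with degree/label tie-breaks", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  ts <- topology(star, seed = 1)
  ks <- keystones(ts, k = 3)
  expect_identical(ks$node[1], "hub")
  expect_equal(ks$betweenness[1], choose(4, 2))   # (n-1)(n-2)/2 = 6

  # all-zero betweenness: falls back to degree then label
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(4))
  igraph::V(tri2)$name <- c("b1", "b2", "b3", "a1", "a2", "a3", "a4")
  tt <- topology(tri2, seed = 1)
  expect_true(all(tt$nodes$betweenness == 0))
  kk <- keystones(tt, k = 7)
  expect_identical(kk$node[1:4], c("a1", "a2", "a3", "a4"))  # degree 3 first
  expect_identical(kk$node[5:7], c("b1", "b2", "b3"))
  expect_warning(keystones(tt, k = 10), "truncating")
})

test_that("module niche preference tallies are conserved and correct", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(3))
  igraph::V(g)$name <- paste0("g", 1:6)
  topo <- topology(g, seed = 1)
  # genera g1-g3 peak in sediment, g4-g6 in air
  niches <- rep(c("sediment", "air", "rock", "water"), each = 2)
  m <- matrix(1.0, 8, 6, dimnames = list(paste0("s", 1:8), paste0("g", 1:6)))
  m[niches == "sediment", 1:3] <- 10
  m[niches == "air", 4:6] <- 10
  meta <- sample_metadata(data.frame(sample_id = paste0("s", 1:8),
                                     cave = "c", niche = niches))
  mnp <- module_niche_preference(topo, m, meta)
  expect_identical(sort(mnp$modules$majority_niche), c("air", "sediment"))
  expect_true(all(rowSums(mnp$modules[, CAVE_NICHES]) == mnp$modules$size))
  sed_mod <- mnp$modules[mnp$modules$majority_niche == "sediment", ]
  expect_identical(sed_mod$sediment, 3L)
  expect_identical(sed_mod$size, 3L)
})

test_that("cooccurrence_network recovers planted blocks end to end", {
  d <- generate_dataset(synthetic_spec(seed = 71))
  filtered <- filter_rare_otus(d$counts)
  genus <- aggregate_to_genus(filtered, d$taxonomy)
  net <- cooccurrence_network(genus, d$metadata,
                              taxonomy = attr(genus, "genus_taxonomy"))
  expect_gt(nrow(net$edges), 50)
  expect_true(all(net$edges$rho > 0.6))
  expect_true(all(net$edges$q < 0.01))
  expect_true("phylum" %in% igraph::vertex_attr_names(net$graph))
  topo <- topology(net, seed = 5)
  expect_equal(topo$average_degree, 2 * topo$n_edges / topo$n_nodes)
  expect_gte(topo$diameter, topo$average_path_length)
  expect_true(topo$modularity >= -0.5 && topo$modularity <= 1)
  # the topology is deterministic under the seed
  topo2 <- topology(net, seed = 5)
  expect_identical(topo$nodes$module, topo2$nodes$module)
})
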