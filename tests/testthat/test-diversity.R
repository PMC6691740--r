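test_that("alpha diversity formulas match their closed forms", {
  expect_equal(shannon(c(5, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(2, 1, 1)), -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), "all-zero")

  # S_obs = 5, F1 = 2, F2 = 1
  x <- c(1, 1, 2, 5, 9)
  expect_equal(chao1(x), 5 + 2^2 / (2 * 1))                 # 7.0
  expect_equal(chao1(x, bias_corrected = TRUE),
               5 + 2 * 1 / (2 * 2))                          # 5.5
  expect_equal(chao1(c(3, 4, 5)), 3)                         # no singletons
  expect_equal(goods_coverage(c(3, 4, 5))           , 1)     # F1 = 0
  expect_equal(goods_coverage(c(1, 1, rep(49, 2))), 1 - 2 / 100)
  expect_equal(goods_coverage(rep(1, 7)), 0)                 # all singletons
})

test_that("alpha diversity invariants hold on random samples", {
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- stats::rpois(60, lambda = sample(1:4, 1))
      if (sum(x) == 0) x[1] <- 1L
      s_obs <- sum(x > 0)
      expect_gte(chao1(x, bias_corrected = TRUE), s_obs)
      expect_lte(shannon(x), log(max(s_obs, 1)) + 1e-12)
      expect_gte(goods_coverage(x), 0)
      expect_lte(goods_coverage(x), 1)
    }
  })
  a <- alpha_diversity(fixture_counts())
  expect_identical(names(a), c("sample_id", "observed_otus", "chao1",
                               "shannon", "goods_coverage"))
  expect_true(all(a$chao1 >= a$observed_otus))
})

test_that("Bray-Curtis matches its formula and the vegan oracle", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  colnames(m) <- paste0("t", 1:3)
  expect_equal(unclass(bray_curtis(m))["a", "b"], 0.5)
  same <- rbind(x = c(2, 3, 1), y = c(2, 3, 1))
  colnames(same) <- paste0("t", 1:3)
  expect_equal(unclass(bray_curtis(same))["x", "y"], 0)
  disj <- rbind(x = c(2, 0, 0), y = c(0, 3, 1))
  colnames(disj) <- paste0("t", 1:3)
  expect_equal(unclass(bray_curtis(disj))["x", "y"], 1)

  withr::with_seed(21, {
    r <- matrix(stats::rpois(10 * 15, 5) + 0.0, 10, 15,
                dimnames = list(paste0("s", 1:10), paste0("t", 1:15)))
    r[1, 1:7] <- 0
    d <- unclass(bray_curtis(r))
    oracle <- as.matrix(vegan::vegdist(r, method = "bray"))
    expect_lt(max(abs(d - oracle)), 1e-12)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  })
})

test_that("weighted UniFrac has the stated limits and matches phyloseq", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")  # star, unit branches
  m <- rbind(s1 = c(A = 1, B = 0, C = 0, D = 0),
             s2 = c(A = 0, B = 1, C = 0, D = 0))
  raw <- weighted_unifrac(m, tr, normalized = FALSE)
  expect_equal(unclass(raw)["s1", "s2"], 2)          # L1 distance on a star
  # identical samples at distance zero
  m2 <- rbind(s1 = c(A = 2, B = 1, C = 3, D = 0),
              s2 = c(A = 2, B = 1, C = 3, D = 0))
  expect_equal(unclass(weighted_unifrac(m2, tr))["s1", "s2"], 0)
  # star tree raw WU equals L1 on relative abundances, any profile
  withr::with_seed(3, {
    p <- matrix(stats::rexp(8), 2, 4,
                dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
    p <- p / rowSums(p)
    expect_equal(unclass(weighted_unifrac(p, tr, normalized = FALSE))[1, 2],
                 sum(abs(p[1, ] - p[2, ])))
  })
  expect_error(weighted_unifrac(rbind(s1 = c(E = 1, A = 1),
                                      s2 = c(E = 2, A = 1)), tr),
               "missing from tree: E")

  # independent oracle on a random dataset
  withr::with_seed(31, {
    ids <- paste0("t", 1:12)
    tree <- generate_tree(ids, seed = 99)
    counts <- matrix(stats::rpois(6 * 12, 8) + 0.0, 6, 12,
                     dimnames = list(paste0("s", 1:6), ids))
    counts[counts == 0] <- 1
    mine <- unclass(weighted_unifrac(counts, tree, normalized = FALSE))
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(t(counts), taxa_are_rows = TRUE),
      phyloseq::phy_tree(tree))
    oracle <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                          normalized = FALSE))
    expect_lt(max(abs(mine - oracle[rownames(mine), colnames(mine)])), 1e-10)
  })
})

test_that("normalized weighted UniFrac is bounded and symmetric", {
  withr::with_seed(17, {
    ids <- paste0("t", 1:20)
    tree <- generate_tree(ids, seed = 5)
    counts <- matrix(stats::rpois(10 * 20, 6) + 0.0, 10, 20,
                     dimnames = list(paste0("s", 1:10), ids))
    counts[rowSums(counts) == 0, 1] <- 1
    d <- unclass(weighted_unifrac(counts, tree, normalized = TRUE))
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
    expect_equal(d, t(d))
  })
})

test_that("the Sorensen partition obeys its closed forms and identity", {
  # a = 2, b = 1, c = 3
  x <- c(1, 1, 1, 0, 0, 0)      # a = {1,2}, b = {3}, c = {4,5,6}
  y <- c(1, 1, 0, 1, 1, 1)
  res <- beta_partition_pair(x, y)
  expect_equal(res[["beta_sor"]], 0.5)
  expect_equal(res[["beta_sim"]], 1 / 3)
  expect_equal(res[["beta_sne"]], 1 / 6)
  # nested pair: no turnover
  nested <- beta_partition_pair(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(nested[["beta_sim"]], 0)
  # equal-richness full replacement: pure turnover
  repl <- beta_partition_pair(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(repl[["beta_sne"]], 0)
  expect_equal(repl[["beta_sor"]], repl[["beta_sim"]])
  expect_error(beta_partition_pair(c(0, 0), c(1, 0)), "1 species")

  withr::with_seed(9, {
    for (i in 1:50) {
      a <- stats::rbinom(30, 1, 0.5); b <- stats::rbinom(30, 1, 0.5)
      if (!any(a > 0)) a[1] <- 1
      if (!any(b > 0)) b[1] <- 1
      r <- beta_partition_pair(a, b)
      expect_lt(abs(r[["beta_sor"]] - r[["beta_sim"]] - r[["beta_sne"]]),
                1e-12)
      expect_true(all(r >= -1e-12 & r <= 1 + 1e-12))
    }
  })
})

test_that("Venn region counts partition the detected OTUs", {
  t <- fixture_counts()                     # 3 samples
  groups <- c("air", "water", "air")
  v <- venn_counts(t, groups)
  expect_identical(sum(v$n_otus), ncol(t))  # every OTU detected somewhere
  # an OTU present everywhere lands in the full intersection
  expect_gte(v$n_otus[v$subset == "air&water"], 1L)

  # 10-OTU fixture vs exhaustive enumeration
  withr::with_seed(13, {
    m <- matrix(stats::rbinom(8 * 10, 3, 0.4), 8, 10,
                dimnames = list(paste0("s", 1:8), paste0("o", 1:10)))
    m[rowSums(m) == 0, 1] <- 1L
    g <- rep(c("air", "water", "rock", "sediment"), each = 2)
    v2 <- venn_counts(count_table(m), g)
    for (i in seq_len(nrow(v2))) {
      want <- strsplit(v2$subset[i], "&", fixed = TRUE)[[1]]
      brute <- sum(vapply(seq_len(ncol(m)), function(j) {
        pres <- unique(g[m[, j] > 0])
        setequal(pres, want)
      }, NA))
      expect_identical(v2$n_otus[i], brute)
    }
  })
})
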