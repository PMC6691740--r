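test_that("rare-OTU filter applies the whole-table proportion rule", {
  # one read out of 200,000 is 5e-6 < 1e-5 and must go
  m <- matrix(c(1L, 99999L, 100000L), 1, 3,
              dimnames = list("s1", c("rare", "big1", "big2")))
  t <- count_table(m)
  f <- filter_rare_otus(t)
  expect_identical(colnames(f), c("big1", "big2"))
  # a tiny threshold keeps everything with >= 1 read
  expect_identical(ncol(filter_rare_otus(t, threshold = 1e-12)), 3L)
  expect_error(filter_rare_otus(t, threshold = 0), "in \\(0,1\\)")
  expect_error(filter_rare_otus(t, threshold = 1), "in \\(0,1\\)")
})

test_that("filter survivors match brute-force recomputation", {
  t <- fixture_counts()
  for (thr in c(0.05, 0.1, 0.2)) {
    keep_brute <- colnames(t)[vapply(seq_len(ncol(t)), function(j)
      sum(t[, j]) / sum(t) >= thr, NA)]
    expect_identical(colnames(filter_rare_otus(t, thr)), keep_brute)
  }
})

test_that("rarefaction is an exact without-replacement subsample", {
  t <- fixture_counts()                     # row sums 10, 11, 8
  r <- rarefy(t, depth = 8, seed = 3)
  expect_true(all(rowSums(r) == 8))
  expect_true(all(unclass(r) <= unclass(t)[rownames(r), ]))
  expect_identical(attr(r, "method"), "rarefied")
  # depth = sample total leaves counts unchanged
  one <- count_table(matrix(c(5L, 3L, 2L), 1, 3,
                            dimnames = list("s", c("a", "b", "c"))))
  expect_identical(unclass(rarefy(one, depth = 10, seed = 1))[, ],
                   matrix(c(5, 3, 2), 1, 3,
                          dimnames = list("s", c("a", "b", "c")))[, ])
  expect_warning(rarefy(t, depth = 11, seed = 1), "dropping 2 sample")
  expect_error(rarefy(t, depth = 0), "depth")
})

test_that("rarefied means match the hypergeometric expectation", {
  one <- count_table(matrix(c(5L, 3L, 2L), 1, 3,
                            dimnames = list("s", c("a", "b", "c"))))
  B <- 4000
  draws <- vapply(seq_len(B),
                  function(b) unclass(rarefy(one, depth = 5, seed = b))[1, ],
                  numeric(3))
  mean_hat <- rowMeans(draws)
  expected <- 5 * c(5, 3, 2) / 10
  se <- apply(draws, 1, stats::sd) / sqrt(B)
  expect_true(all(abs(mean_hat - expected) <= 3 * se + 1e-9))
})

test_that("rarefaction commutes with taxon permutation (canonical draw order)", {
  t <- fixture_counts()
  perm <- c(3L, 1L, 4L, 2L)
  tp <- count_table(unclass(t)[, perm])
  r1 <- rarefy(t, depth = 8, seed = 9)
  r2 <- rarefy(tp, depth = 8, seed = 9)
  expect_identical(unclass(r2)[, ], unclass(r1)[, perm])
})

test_that("CSS scaling follows the quantile-sum definition", {
  # nonzero counts [1,2,3,4], q = 0.5 -> quantile value 2 -> s = 1 + 2 = 3
  m <- matrix(c(1L, 2L, 3L, 4L, 0L), 1, 5,
              dimnames = list("s1", paste0("t", 1:5)))
  css <- css_normalize(count_table(m))
  expect_equal(attr(css, "scaling_factors")[["s1"]], 3)
  expect_equal(unclass(css)[1, ], c(1, 2, 3, 4, 0) * 1000 / 3,
               ignore_attr = TRUE)
  # identical samples get identical factors; output proportional to input
  two <- count_table(rbind(s1 = c(a = 3L, b = 5L, c = 9L),
                           s2 = c(a = 3L, b = 5L, c = 9L)))
  c2 <- css_normalize(two)
  s <- attr(c2, "scaling_factors")
  expect_equal(s[["s1"]], s[["s2"]])
  # doubling one sample's counts doubles s_j, leaving its row unchanged
  dbl <- count_table(rbind(s1 = c(a = 3L, b = 5L, c = 9L),
                           s2 = c(a = 6L, b = 10L, c = 18L)))
  cd <- css_normalize(dbl)
  expect_equal(attr(cd, "scaling_factors")[["s2"]],
               2 * attr(cd, "scaling_factors")[["s1"]])
  expect_equal(unclass(cd)[1, ], unclass(cd)[2, ])
})

test_that("relative and CPM follow their arithmetic definitions", {
  t <- count_table(matrix(c(2L, 2L), 1, 2, dimnames = list("s", c("a", "b"))))
  expect_equal(unclass(to_relative(t))[1, ], c(a = 0.5, b = 0.5))
  t2 <- count_table(matrix(c(1L, 0L, 3L), 1, 3,
                           dimnames = list("s", c("a", "b", "c"))))
  expect_equal(unclass(to_cpm(t2))[1, ], c(a = 250000, b = 0, c = 750000))
  expect_equal(unclass(to_relative(t2)) * 1e6, unclass(to_cpm(t2)),
               ignore_attr = TRUE)
})

test_that("all normalizations preserve zeros", {
  t <- fixture_counts()
  zero <- unclass(t) == 0
  for (norm in list(to_relative(t), to_cpm(t), css_normalize(t),
                    rarefy(t, depth = 8, seed = 1)))
    expect_true(all(unclass(norm)[rownames(t), ][zero] == 0))
})

test_that("genus aggregation sums counts and pools unassigned OTUs", {
  m <- matrix(c(3L, 4L, 2L, 1L, 6L,
                1L, 2L, 3L, 4L, 5L), 2, 5, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("o", 1:5)))
  tax <- taxonomy_map(data.frame(
    taxon_id = paste0("o", 1:5),
    domain = "Bacteria", phylum = "P", class = "C", order = "O",
    family = c("F1", "F1", "F2", "F2", "F3"),
    genus = c("Ga", "Ga", "Gb", "", ""),
    stringsAsFactors = FALSE))
  g <- aggregate_to_genus(count_table(m), tax)
  # Ga (o1+o2), Gb, F2__unclassified, F3__unclassified
  expect_setequal(colnames(g), c("Ga", "Gb", "F2__unclassified",
                                 "F3__unclassified"))
  expect_identical(unclass(g)[, "Ga"], c(s1 = 7L, s2 = 3L))
  expect_identical(sum(g), sum(m))        # conservation
  expect_error(aggregate_to_genus(count_table(m), tax[-2, ]),
               "absent from taxonomy")
})

test_that("a hand-counted fixture with 3 genera and 2 unassigned families gives 5 rows", {
  m <- matrix(rep(1L, 7), 1, 7, dimnames = list("s", paste0("o", 1:7)))
  tax <- taxonomy_map(data.frame(
    taxon_id = paste0("o", 1:7), domain = "B", phylum = "P", class = "C",
    order = "O", family = c("Fx", "Fx", "Fy", "Fy", "Fz", "Fu", "Fv"),
    genus = c("G1", "G1", "G2", "G3", "G3", "", ""),
    stringsAsFactors = FALSE))
  g <- aggregate_to_genus(count_table(m), tax)
  expect_identical(ncol(g), 5L)
})

test_that("aggregation commutes with relative normalization", {
  d <- generate_dataset(synthetic_spec(n_caves = 2,
                                       samples_per_cave_per_niche = 2,
                                       n_taxa = 150, depth = 3000, seed = 8))
  g_then_rel <- unclass(to_relative(aggregate_to_genus(d$counts, d$taxonomy)))
  rel <- unclass(to_relative(d$counts))
  # direct recomputation: group-sum the relative abundances with the same
  # labelling rule
  tx <- d$taxonomy[match(colnames(d$counts), d$taxonomy$taxon_id), ]
  lab <- tx$genus
  for (i in which(lab == "")) {
    lin <- as.character(tx[i, c("domain", "phylum", "class", "order",
                                "family", "genus", "species")])
    lab[i] <- paste0(lin[max(which(lin != ""))], "__unclassified")
  }
  manual <- t(rowsum(t(rel), lab))
  expect_lt(max(abs(manual[, colnames(g_then_rel)] - g_then_rel)), 1e-12)
})
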