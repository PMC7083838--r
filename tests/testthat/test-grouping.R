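dist3 <- function(ab, ac, bc, labels = c("A", "B", "C")) {
  d <- matrix(0, 3, 3, dimnames = list(labels, labels))
  d["A", "B"] <- d["B", "A"] <- ab
  d["A", "C"] <- d["C", "A"] <- ac
  d["B", "C"] <- d["C", "B"] <- bc
  d
}

two_block_dist <- function() {
  labels <- c("A1", "A2", "B1", "B2")
  d <- matrix(0.9, 4, 4, dimnames = list(labels, labels))
  d[1:2, 1:2] <- 0.1; d[3:4, 3:4] <- 0.1
  diag(d) <- 0
  d
}

test_that("complete linkage agglomerates by the maximum rule", {
  hc <- complete_linkage(dist3(0.1, 0.9, 0.9))
  expect_equal(hc$height, c(0.1, 0.9))
  hc <- complete_linkage(two_block_dist())
  expect_equal(max(hc$height), 0.9)
  expect_equal(sort(hc$height), c(0.1, 0.1, 0.9))
  # all-equal distances: repeated merge height, flat cut below gives singletons
  d <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3])); diag(d) <- 0
  hc <- complete_linkage(d)
  expect_equal(unique(hc$height), 0.5)
  expect_equal(length(unique(flat_clusters(hc, 0.4))), 3)
  dd <- dist3(0.1, NaN, 0.9)
  expect_error(complete_linkage(dd), "non-finite")
})

test_that("flat clustering cuts by cophenetic distance", {
  hc <- complete_linkage(two_block_dist())
  cl <- flat_clusters(hc, 0.7)
  expect_equal(length(unique(cl)), 2)
  expect_equal(cl[["A1"]], cl[["A2"]])
  expect_equal(cl[["B1"]], cl[["B2"]])
  expect_false(cl[["A1"]] == cl[["B1"]])
  expect_equal(length(unique(flat_clusters(hc, 0.05))), 4)
  expect_equal(length(unique(flat_clusters(hc, 1.5))), 1)
  # cut exactly at a merge height keeps that merge (criterion "distance")
  expect_equal(length(unique(flat_clusters(hc, 0.1))), 2)
  expect_error(flat_clusters(hc, -0.1), "non-negative")
  # within-cluster cophenetic distance never exceeds the threshold
  cop <- cophenetic_matrix(hc)
  for (t in c(0.05, 0.1, 0.7, 1.5)) {
    cl <- flat_clusters(hc, t)
    for (k in unique(cl)) {
      gg <- names(cl)[cl == k]
      if (length(gg) > 1) expect_lte(max(cop[gg, gg]), t)
    }
  }
})

test_that("flat clustering is monotone: raising the threshold only merges", {
  set.seed(77)
  m <- random_binary_matrix(12, 30)
  hc <- complete_linkage(distance_matrix(m))
  prev <- flat_clusters(hc, 0)
  for (t in seq(0.05, 2, by = 0.1)) {
    cur <- flat_clusters(hc, t)
    # refinement: genomes together at the lower threshold stay together
    agree <- outer(prev, prev, "==")
    agree2 <- outer(cur, cur, "==")
    expect_true(all(agree2[agree]))
    prev <- cur
  }
})

test_that("cophenetic distances dominate input distances (complete linkage)", {
  set.seed(31)
  for (i in 1:5) {
    m <- random_binary_matrix(10, 25)
    d <- distance_matrix(m)
    cop <- cophenetic_matrix(complete_linkage(d))
    expect_true(all(cop[rownames(d), colnames(d)] >= d - 1e-12))
  }
})

test_that("mds is deterministic, prefix-nested and exact on realizable input", {
  d <- dist3(1, 1, 1)
  e1 <- mds_embed(d, n_init = 5, seed = 42)
  e2 <- mds_embed(d, n_init = 5, seed = 42)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$stress, e2$stress)
  # equilateral triangle: essentially zero stress, equal pairwise distances
  dd <- as.matrix(stats::dist(e1$coords))
  side <- dd[lower.tri(dd)]
  expect_lt(max(side) - min(side), 1e-3)
  expect_lt(e1$stress, 1e-6)
  # best-of-20 can never be worse than best-of-1 on the same seed stream
  set.seed(202)
  m <- random_binary_matrix(9, 20)
  d <- distance_matrix(m)
  s1 <- mds_embed(d, n_init = 1, seed = 7)$stress
  s20 <- mds_embed(d, n_init = 20, seed = 7)$stress
  expect_lte(s20, s1)
  expect_error(mds_embed(d[1:2, 1:2], n_init = 1, seed = 1), "at least 3")
})

test_that("planar distances are recovered with vanishing stress", {
  set.seed(13)
  pts <- matrix(stats::rnorm(16), 8, 2)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(letters[1:8], letters[1:8])
  e <- mds_embed(d, n_init = 10, seed = 4)
  expect_lt(e$stress, 1e-4)
})

test_that("mds stress is invariant under label permutation of the input", {
  set.seed(88)
  m <- random_binary_matrix(8, 22)
  d <- distance_matrix(m)
  p <- sample(nrow(d))
  e1 <- mds_embed(d, n_init = 5, seed = 11)
  e2 <- mds_embed(d[p, p], n_init = 5, seed = 11)
  expect_equal(e1$stress, e2$stress, tolerance = 1e-6)
})

test_that("congruence computes the adjusted Rand index", {
  x <- c(g1 = 1, g2 = 1, g3 = 2, g4 = 2)
  expect_equal(congruence(x, c(g1 = "a", g2 = "a", g3 = "b", g4 = "b")), 1)
  singletons <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
  one_block <- c(g1 = "a", g2 = "a", g3 = "a", g4 = "a")
  expect_equal(congruence(singletons, one_block), 0)
  expect_error(congruence(x, c(g1 = 1, g2 = 1, g9 = 2, g4 = 2)), "same genomes")
  # against the independent pair-counting oracle on random partitions
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    a <- setNames(sample(1:4, n, replace = TRUE), sprintf("g%02d", 1:n))
    b <- setNames(sample(1:4, n, replace = TRUE), sprintf("g%02d", 1:n))
    expect_equal(congruence(a, b), oracle_ari(a, b[names(a)]), tolerance = 1e-12)
  }
})

test_that("threshold presets carry the published cut heights", {
  th <- epr_thresholds()
  expect_equal(th[["inner"]], 0.15)
  expect_equal(th[["genus"]], 0.3)
  expect_equal(th[["phylum"]], 0.7)
})
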