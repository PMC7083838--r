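test_that("annotation tables parse with derived indecision flags", {
  ann <- read_annotations(annot_fixture_path())
  expect_equal(nrow(ann), 3L)
  expect_equal(ann$family, c("GH1", "GH3", "GH76"))
  expect_equal(ann$functions[[1]], "3.2.1.37")
  expect_false(ann$indecisive[1])
  expect_equal(ann$functions[[2]], c("3.2.1.21", "3.2.1.74"))
  expect_true(ann$indecisive[2])
  expect_equal(ann$functions[[3]], "unknown")
  expect_false(ann$indecisive[3])
})

test_that("malformed annotation rows raise errors naming the line", {
  p <- write_tsv_text(c("genome_id\tprotein_id\tfamily\tfunctions",
                        "g1\tp1\tGH1\t3.2.1.37",
                        "g1\tp2\tXX9\t3.2.1.4"))
  expect_error(read_annotations(p), "line 3")
  p <- write_tsv_text(c("genome_id\tprotein_id\tfamily\tfunctions",
                        "g1\tp1\tGH1\t3.2.banana"))
  expect_error(read_annotations(p), "line 2")
  p <- write_tsv_text("genome_id\tprotein_id\tfamily\tfunctions")
  expect_error(read_annotations(p), "empty")
})

test_that("subfamily tokens collapse by default and can be retained", {
  p <- write_tsv_text(c("genome_id\tprotein_id\tfamily\tfunctions",
                        "g1\tp1\tGH5_5\t3.2.1.4"))
  expect_equal(read_annotations(p)$family, "GH5")
  expect_equal(read_annotations(p, collapse_subfamilies = FALSE)$family, "GH5_5")
})

test_that("observation ids canonicalize from either order and separator", {
  expect_equal(obs_id("GH1", "3.2.1.37"), "GH1:3.2.1.37")
  for (form in c("GH1:3.2.1.37", "3.2.1.37:GH1", "3.2.1.37;GH1", "GH1;3.2.1.37")) {
    p <- parse_obs_id(form)
    expect_equal(p$id, "GH1:3.2.1.37")
    expect_equal(p$family, "GH1")
    expect_equal(p$fun, "3.2.1.37")
  }
  expect_equal(parse_obs_id("GH76:unknown")$fun, "unknown")
  expect_error(parse_obs_id("GH1:GH2"), "exactly one family")
  expect_error(obs_id("GH1", "3.2.1"), "invalid EC")
})

test_that("annotation write/read round trip is the identity", {
  ann <- random_records(40, seed = 11)
  p <- tempfile(fileext = ".tsv")
  write_annotations(ann, p)
  back <- read_annotations(p)
  expect_equal(back$protein_id, ann$protein_id)
  expect_equal(back$family, ann$family)
  expect_equal(unclass(back$functions), unclass(ann$functions),
               ignore_attr = TRUE)
  expect_equal(back$indecisive, ann$indecisive)
})

test_that("secretion call tables parse strictly", {
  p <- write_tsv_text(c("protein_id\ttool1\ttool2\ttool3", "p1\t1\t1\t0"))
  calls <- read_secretion_calls(p)
  expect_equal(unname(calls["p1", ]), c(TRUE, TRUE, FALSE))
  p <- write_tsv_text(c("protein_id\ttool1\ttool2\ttool3",
                        "p1\t1\t1\t0", "p1\t0\t0\t0"))
  expect_error(read_secretion_calls(p), "duplicate")
  p <- write_tsv_text(c("protein_id\ttool1", "p1\t1"))
  expect_error(read_secretion_calls(p), "tool")
})

test_that("matrix TSV round trips exactly; asymmetry is rejected", {
  set.seed(42)
  m <- random_binary_matrix(5, 8)
  p <- tempfile(fileext = ".tsv")
  write_matrix(m, p)
  expect_identical(read_matrix(p), m)

  d <- distance_matrix(m)
  write_matrix(d, p)
  expect_lt(max(abs(read_matrix(p) - d)), 1e-12)

  bad <- d; bad[1, 2] <- bad[1, 2] + 1e-6
  expect_error(write_matrix(bad, p), "asymmetric")
  expect_error(write_matrix(m[0, , drop = FALSE], p), "empty")
})

test_that("newick export splits a 2-leaf merge ultrametrically", {
  hc <- complete_linkage(matrix(c(0, 0.4, 0.4, 0),
                                2, 2, dimnames = list(c("A", "B"), c("A", "B"))))
  p <- tempfile(fileext = ".nwk")
  write_newick(hc, p)
  phy <- ape::read.tree(p)
  el <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(el[c("A", "B")]), c(0.2, 0.2))
  expect_equal(unname(ape::cophenetic.phylo(phy)["A", "B"]), 0.4)
})

test_that("newick round trip reproduces all cophenetic distances to 1e-9", {
  set.seed(7)
  m <- random_binary_matrix(9, 25)
  d <- distance_matrix(m)
  hc <- complete_linkage(d)
  p <- tempfile(fileext = ".nwk")
  write_newick(hc, p)
  phy <- ape::read.tree(p)
  cop_tree <- ape::cophenetic.phylo(phy)
  cop_hc <- cophenetic_matrix(hc)
  expect_lt(max(abs(cop_tree[rownames(cop_hc), colnames(cop_hc)] - cop_hc)), 1e-9)
})

test_that("degenerate dendrograms are refused by write_newick", {
  fake <- structure(list(labels = "A", height = numeric(0)), class = "hclust")
  expect_error(write_newick(fake, tempfile()), "at least 2")
  hc <- complete_linkage(matrix(c(0, 1, 1, 0), 2, 2,
                                dimnames = list(c("A", "B"), c("A", "B"))))
  hc$height <- NaN
  expect_error(write_newick(hc, tempfile()), "non-finite")
})

test_that("metadata reader enforces uniqueness and hierarchy", {
  hdr <- "genome_id\tspecies\tsection\tgenus\tphylum\tassembly_status"
  p <- write_tsv_text(c(hdr, "g1\ts1\tA\tGa\tP1\tfull", "g2\ts2\tA\tGb\tP1\tfull"))
  expect_error(read_metadata(p), "hierarchical")
  p <- write_tsv_text(c(hdr, "g1\ts1\tA\tGa\tP1\tfull", "g1\ts2\tA\tGa\tP1\tfull"))
  expect_error(read_metadata(p), "duplicate")
  p <- write_tsv_text(c(hdr, "g1\ts1\tA\tGa\tP1\tfull", "g2\ts2\tB\tGa\tP1\tpartial"))
  md <- read_metadata(p)
  expect_equal(md$assembly_status, c("full", "partial"))
})
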