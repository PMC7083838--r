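# Shared fixtures and independent oracles for the test suite.

# naive positionwise Yule oracle, deliberately scalar and loop-based
oracle_yule <- function(u, v) {
  ctt <- cff <- ctf <- cft <- 0L
  for (i in seq_along(u)) {
    if (u[i] == 1 && v[i] == 1) ctt <- ctt + 1L
    else if (u[i] == 0 && v[i] == 0) cff <- cff + 1L
    else if (u[i] == 1 && v[i] == 0) ctf <- ctf + 1L
    else cft <- cft + 1L
  }
  r <- ctf * cft
  if (r == 0) 0 else 2 * r / (ctt * cff + r)
}

oracle_distance_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- oracle_yule(m[i, ], m[j, ])
  d
}

# independent ARI oracle via explicit pair counting (alternative closed form)
oracle_ari <- function(x, y) {
  n <- length(x)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] == x[j]; sy <- y[i] == y[j]
    if (sx && sy) a <- a + 1
    else if (sx && !sy) b <- b + 1
    else if (!sx && sy) cc <- cc + 1
    else d <- d + 1
  }
  denom <- (a + b) * (b + d) + (a + cc) * (cc + d)
  if (denom == 0) return(1)
  2 * (a * d - b * cc) / denom
}

# valid observation ids usable as abstract set elements a..f
obs_pool <- c(a = "GH1:3.2.1.1", b = "GH2:3.2.1.2", c = "GH3:3.2.1.3",
              d = "CE1:3.1.1.4", e = "PL1:4.2.2.5", f = "AA9:1.14.99.6")

write_tsv_text <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

annot_fixture_path <- function() {
  write_tsv_text(c(
    "genome_id\tprotein_id\tfamily\tfunctions",
    "g1\tp1\tGH1\t3.2.1.37",
    "g1\tp2\tGH3\t3.2.1.21;3.2.1.74",
    "g1\tp3\tGH76\tunknown"))
}

# random annotation table + secretion calls for property tests
random_records <- function(n, genome = "g1", seed = 1) {
  set.seed(seed)
  fams <- c("GH1", "GH2", "GH5", "CE1", "PL4", "AA9")
  recs <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1, prob = c(.6, .3, .1))
    funs <- sprintf("3.2.1.%d", sample(1:8, k))
    list(pid = sprintf("p%03d", i), fam = sample(fams, 1), funs = funs)
  })
  data.frame(genome_id = genome,
             protein_id = vapply(recs, `[[`, character(1), "pid"),
             family = vapply(recs, `[[`, character(1), "fam"),
             functions = I(lapply(recs, `[[`, "funs")),
             indecisive = vapply(recs, function(r) length(r$funs) > 1, logical(1)),
             stringsAsFactors = FALSE)
}

random_binary_matrix <- function(m, n, p = 0.4) {
  mat <- matrix(as.integer(stats::runif(m * n) < p), m, n,
                dimnames = list(sprintf("g%02d", seq_len(m)),
                                sprintf("o%02d", seq_len(n))))
  mat
}

# scan candidate thresholds (merge-height midpoints) and return the best ARI
# of flat clustering against reference labels
best_ari_over_cuts <- function(dend, labels) {
  h <- sort(unique(dend$height))
  cuts <- c(h[1] / 2, (h[-length(h)] + h[-1]) / 2, max(h) + 1)
  best <- -1
  for (t in cuts) {
    cl <- flat_clusters(dend, t)
    best <- max(best, congruence(cl, labels[names(cl)]))
  }
  best
}
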