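#' Named flat-clustering threshold presets
#'
#' `inner` (0.15) and `genus` (0.3) are the two dendrogram rings used when
#' mapping sections and genera; `phylum` (0.7) separates the two Dikarya
#' phyla.
#'
#' @return named numeric vector of thresholds.
#' @export
epr_thresholds <- function() c(inner = 0.15, genus = 0.3, phylum = 0.7)

#' Complete-linkage hierarchical clustering
#'
#' Agglomerates genomes on a Yule distance matrix, merging at each step the
#' pair of clusters with the smallest *maximum* inter-cluster distance.
#' Complete linkage guarantees non-decreasing merge heights.  Ties are
#' broken by the deterministic rule of [stats::hclust()].
#'
#' @param d symmetric distance matrix (e.g. from [distance_matrix()]) or a
#'   `dist` object.
#' @return an `hclust` object; leaf labels are genome ids.
#' @export
complete_linkage <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (any(is.na(d)) || any(!is.finite(d))) stop("non-finite distances")
  if (nrow(d) < 2L) stop("need at least 2 genomes")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is asymmetric")
  stats::hclust(stats::as.dist(d), method = "complete")
}

#' Flat clusters by cutting a dendrogram at a distance threshold
#'
#' Cuts every merge whose height exceeds `threshold` (criterion "distance"):
#' all members of one flat cluster have cophenetic distance at most the
#' threshold.  Cluster indices are assigned by first appearance in the input
#' label order.
#'
#' @param dendrogram `hclust` object from [complete_linkage()].
#' @param threshold non-negative cut height.
#' @return named integer vector of cluster indices (1-based), with the
#'   threshold stored in `attr(, "threshold")`.
#' @export
flat_clusters <- function(dendrogram, threshold) {
  if (threshold < 0) stop("threshold must be non-negative")
  cl <- stats::cutree(dendrogram, h = threshold)
  # relabel clusters in order of first appearance over the label order
  first <- unique(unname(cl))
  out <- match(cl, first)
  names(out) <- names(cl)
  attr(out, "threshold") <- threshold
  out
}

#' Cophenetic distances of a dendrogram
#'
#' The cophenetic distance of two leaves is the merge height at which they
#' first join.
#'
#' @param dendrogram `hclust` object.
#' @return symmetric labeled matrix.
#' @export
cophenetic_matrix <- function(dendrogram) {
  as.matrix(stats::cophenetic(dendrogram))
}

kruskal_stress1 <- function(delta, conf) {
  dd <- as.matrix(stats::dist(conf))
  lo <- lower.tri(delta)
  sqrt(sum((dd[lo] - delta[lo])^2) / sum(dd[lo]^2))
}

smacof_fit <- function(delta, x0, max_iter = 300L, tol = 1e-12) {
  m <- nrow(delta)
  x <- x0
  prev <- Inf
  for (it in seq_len(max_iter)) {
    dd <- as.matrix(stats::dist(x))
    raw <- sum((dd[lower.tri(dd)] - delta[lower.tri(delta)])^2)
    if (prev - raw < tol * max(prev, 1e-300)) break
    prev <- raw
    # Guttman transform
    b <- ifelse(dd > 0, -delta / dd, 0)
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- b %*% x / m
  }
  x
}

#' Metric MDS with random restarts, keeping the lowest-stress map
#'
#' Embeds genomes into the plane with metric multidimensional scaling
#' (SMACOF majorization), restarted from `n_init` random configurations
#' drawn from one seeded stream; the configuration with the smallest final
#' Kruskal stress-1 is returned.  With the same `(seed, n_init)` the result
#' is byte-identical across runs, and the restarts are prefix-nested: the
#' best of 20 restarts can never have higher stress than the best of 1.
#'
#' @param d symmetric distance matrix.
#' @param n_init number of random initializations (the published map used
#'   50,000; desk-scale analyses use far fewer).
#' @param seed integer seed for the initialization stream.
#' @return object of class `epr_mds`: list with `coords` (m x 2, labeled
#'   rows), `stress` (Kruskal stress-1), `n_init`, `seed`.
#' @export
mds_embed <- function(d, n_init = 50L, seed = 1L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  m <- nrow(d)
  if (m < 3L) stop("need at least 3 genomes for a 2-D embedding")
  if (n_init < 1L) stop("n_init must be at least 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  best_stress <- Inf
  scale0 <- max(d)
  if (scale0 <= 0) scale0 <- 1
  for (i in seq_len(n_init)) {
    x0 <- matrix(stats::runif(m * 2, -scale0, scale0), m, 2)
    x <- smacof_fit(d, x0)
    s <- kruskal_stress1(d, x)
    if (s < best_stress) { best_stress <- s; best <- x }
  }
  rownames(best) <- rownames(d)
  colnames(best) <- c("dim1", "dim2")
  structure(list(coords = best, stress = best_stress,
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "epr_mds")
}

#' @export
print.epr_mds <- function(x, ...) {
  cat("<epr_mds> ", nrow(x$coords), " genomes, stress-1 = ",
      format(x$stress, digits = 6), " (best of ", x$n_init,
      " restarts, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Adjusted Rand index between a clustering and reference labels
#'
#' Chance-corrected agreement between two partitions of the same genomes;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param assignment named vector of cluster labels (e.g. from
#'   [flat_clusters()]).
#' @param truth named vector of reference labels over the same genomes.
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
congruence <- function(assignment, truth) {
  if (is.null(names(assignment)) || is.null(names(truth)) ||
      !setequal(names(assignment), names(truth)))
    stop("assignment and truth must be named over the same genomes")
  truth <- truth[names(assignment)]
  tab <- table(assignment, truth)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  exp_ij <- sum_a * sum_b / ch2(n)
  denom <- (sum_a + sum_b) / 2 - exp_ij
  if (abs(denom) < 1e-12) {
    # both partitions trivial in the same way: identical => perfect agreement
    return(if (sum_ij == sum_a && sum_ij == sum_b) 1 else 0)
  }
  (sum_ij - exp_ij) / denom
}
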