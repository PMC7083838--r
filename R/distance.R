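#' 2x2 contingency counts for two binary profiles
#'
#' Counts, position by position, the observations two genomes share the
#' presence of (`c_tt`), share the absence of (`c_ff`), and carry in one
#' profile but not the other (`c_tf`, `c_ft`).
#'
#' @param u,v equal-length binary (0/1 or logical) vectors.
#' @return named integer vector `c(c_tt, c_ff, c_tf, c_ft)`.
#' @export
contingency <- function(u, v) {
  if (length(u) != length(v)) stop("profiles differ in length")
  u <- as.logical(u); v <- as.logical(v)
  c(c_tt = sum(u & v), c_ff = sum(!u & !v),
    c_tf = sum(u & !v), c_ft = sum(!u & v))
}

#' Yule dissimilarity between two binary profiles
#'
#' \deqn{d = \frac{2\, C_{TF} C_{FT}}{C_{TT} C_{FF} + C_{TF} C_{FT}}}
#'
#' Shared presence and shared absence enter symmetrically, which is why this
#' score (rather than e.g. Jaccard) suits profiles where shared *absence* of
#' an observation is informative.  When `c_tf * c_ft == 0` the numerator
#' vanishes and the score is defined as 0, covering also the degenerate
#' 0/0 case; this matches the convention of the standard scientific-computing
#' implementation.  The score lies in `[0, 2]` and is a dissimilarity, not a
#' metric (the triangle inequality is not guaranteed).
#'
#' @param u,v equal-length binary vectors.
#' @return dissimilarity in `[0, 2]`.
#' @examples
#' yule(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))  # 2/3
#' @export
yule <- function(u, v) {
  ct <- contingency(u, v)
  r <- ct[["c_tf"]] * ct[["c_ft"]]
  if (r == 0) return(0)
  2 * r / (ct[["c_tt"]] * ct[["c_ff"]] + r)
}

#' Yule distance matrix over an observation matrix
#'
#' Computes all pairwise Yule dissimilarities between genome rows with one
#' round of matrix products (`c_tt = M M'` etc.), giving the m x m distance
#' matrix used for clustering and MDS.
#'
#' @param m 0/1 observation matrix, genomes in rows (at least 2 rows, at
#'   least 1 column).
#' @return symmetric numeric matrix with zero diagonal, labels preserved.
#' @export
distance_matrix <- function(m) {
  m <- unclass_obs_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 genomes")
  if (ncol(m) == 0L) stop("observation matrix has no columns")
  storage.mode(m) <- "double"
  w <- 1 - m
  ctt <- tcrossprod(m)
  cff <- tcrossprod(w)
  ctf <- tcrossprod(m, w)
  cft <- t(ctf)
  r <- ctf * cft
  denom <- ctt * cff + r
  d <- ifelse(r == 0, 0, 2 * r / denom)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
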