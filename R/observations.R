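# Scores are kept as exact rationals (num/den, both small integers stored as
# doubles) so that k indecisive 1/k contributions sum to exactly 1 and the
# presence threshold "score >= 1" never falls to floating-point rounding.

rat_gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

rat_add <- function(n1, d1, n2, d2) {
  n <- n1 * d2 + n2 * d1
  d <- d1 * d2
  g <- rat_gcd(n, d)
  if (g > 1) { n <- n / g; d <- d / g }
  c(n, d)
}

new_obs_scores <- function(num, den) {
  structure(list(num = num, den = den), class = "obs_scores")
}

#' @export
as.double.obs_scores <- function(x, ...) {
  out <- x$num / x$den
  names(out) <- names(x$num)
  out
}

#' @export
print.obs_scores <- function(x, ...) {
  cat("<obs_scores> ", length(x$num), " observation(s)\n", sep = "")
  print(as.numeric(x))
  invisible(x)
}

#' Accumulate observation scores for one genome
#'
#' Each secreted, annotated protein record distributes a total mass of 1
#' over its observations: an unambiguous call adds 1 to its single
#' `"FAMILY:EC"` observation, and an indecisive call listing `k` functions
#' adds `1/k` to each (the two-way case scores each a half).  Proteins that
#' fail the secretion consensus contribute nothing.  Scores are exact
#' rationals, so two half-counts reach exactly 1.
#'
#' @param records annotation data.frame (as from [read_annotations()]) for a
#'   single genome.
#' @param secreted character vector of secreted protein ids; only records
#'   whose protein is listed contribute.
#' @return an `obs_scores` object (named rational scores per observation id);
#'   convert with `as.numeric()`.
#' @export
accumulate_scores <- function(records, secreted) {
  if (length(unique(records$genome_id)) > 1L)
    stop("records span more than one genome: ",
         paste(unique(records$genome_id), collapse = ", "))
  keep <- records$protein_id %in% secreted
  num <- numeric(0); den <- numeric(0)
  idx <- which(keep)
  for (i in idx) {
    funs <- records$functions[[i]]
    k <- length(funs)
    ids <- obs_id(rep(records$family[i], k), funs)
    for (id in unique(ids)) {
      w <- sum(ids == id)  # same observation listed twice still sums its mass
      j <- match(id, names(num))
      if (is.na(j)) {
        num[id] <- w; den[id] <- k
        g <- rat_gcd(w, k)
        if (g > 1) { num[id] <- w / g; den[id] <- k / g }
      } else {
        nd <- rat_add(num[j], den[j], w, k)
        num[j] <- nd[1]; den[j] <- nd[2]
      }
    }
  }
  new_obs_scores(num, den)
}

#' Binarize accumulated scores into a presence set
#'
#' An observation is present when its accumulated score reaches at least 1
#' (a single unambiguous protein suffices; a lone two-way indecisive call at
#' 0.5 does not).  Presence is binary: any score at or above 1 counts once,
#' however many redundant proteins contributed.
#'
#' @param scores an `obs_scores` object from [accumulate_scores()], or a
#'   named non-negative numeric vector.
#' @return character vector of present observation ids, sorted.
#' @export
binarize <- function(scores) {
  if (inherits(scores, "obs_scores")) {
    if (any(scores$num < 0)) stop("negative observation score")
    present <- names(scores$num)[scores$num >= scores$den]
  } else {
    if (any(scores < 0)) stop("negative observation score")
    # numeric path: tolerate fp dust just below 1 from external score sums
    present <- names(scores)[scores >= 1 - 1e-9]
  }
  sort(present, method = "radix")
}

#' Build the binary observation matrix
#'
#' Rows are genomes, columns the union of all observation ids (sorted
#' lexicographically); cell `[g, o]` is 1 iff genome `g` carries observation
#' `o`.
#'
#' @param per_genome_presence named list, genome id -> character vector of
#'   present observation ids (e.g. from [binarize()]).
#' @return integer 0/1 matrix with genome rownames and observation colnames.
#' @export
build_matrix <- function(per_genome_presence) {
  ids <- names(per_genome_presence)
  if (is.null(ids) || length(ids) < 2L)
    stop("need a named list of at least 2 genomes")
  if (anyDuplicated(ids))
    stop("duplicate genome_id: ", ids[duplicated(ids)][1])
  cols <- sort(unique(unlist(per_genome_presence, use.names = FALSE)),
               method = "radix")
  m <- matrix(0L, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (g in ids) m[g, per_genome_presence[[g]]] <- 1L
  m
}

#' Drop observations seen in at most one genome
#'
#' Columns with column sum 0 or 1 are removed; this guards the analysis
#' against low-quality genomes contributing private observations.  In the
#' full pipeline the filter is applied for the Dikarya profile only.
#'
#' @param m 0/1 observation matrix from [build_matrix()].
#' @return the matrix without singleton columns.
#' @export
filter_singletons <- function(m) {
  m[, colSums(m) > 1L, drop = FALSE]
}

unclass_obs_matrix <- function(m) as.matrix(m)

#' Per-genome presence sets from annotation and secretion tables
#'
#' Convenience driver: applies the 2-of-3 secretion consensus, accumulates
#' half-count scores per genome, and binarizes.
#'
#' @param annotations annotation data.frame covering one or more genomes.
#' @param secretion_calls logical call matrix from [read_secretion_calls()].
#' @return named list, genome id -> character vector of present observations.
#' @export
genome_presence <- function(annotations, secretion_calls) {
  secreted <- rownames(secretion_calls)[consensus_secreted(secretion_calls)]
  split_idx <- split(seq_len(nrow(annotations)), annotations$genome_id)
  lapply(split_idx, function(i)
    binarize(accumulate_scores(annotations[i, , drop = FALSE], secreted)))
}

#' Full observation-matrix construction
#'
#' Runs [genome_presence()] and [build_matrix()]; under the `"dikarya"`
#' profile, singleton observations are additionally removed.
#'
#' @param annotations annotation data.frame.
#' @param secretion_calls logical call matrix.
#' @param profile `"genus"` (no singleton filter) or `"dikarya"`.
#' @return 0/1 observation matrix.
#' @export
build_observation_matrix <- function(annotations, secretion_calls,
                                     profile = c("genus", "dikarya")) {
  profile <- match.arg(profile)
  m <- build_matrix(genome_presence(annotations, secretion_calls))
  if (profile == "dikarya") m <- filter_singletons(m)
  m
}
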