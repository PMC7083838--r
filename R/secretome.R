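#' Consensus secretion call
#'
#' A protein is taken as secreted when at least two of the three prediction
#' tools call it secreted.
#'
#' @param calls logical vector of length 3, or a logical matrix with three
#'   columns (one row per protein, rownames = protein ids).
#' @return logical scalar, or named logical vector for a matrix input.
#' @examples
#' consensus_secreted(c(TRUE, TRUE, FALSE))  # TRUE
#' @export
consensus_secreted <- function(calls) {
  if (is.matrix(calls)) {
    if (ncol(calls) != 3L) stop("secretion calls must have exactly 3 tool columns")
    return(rowSums(calls) >= 2L)
  }
  if (length(calls) != 3L) stop("exactly 3 secretion calls required per protein")
  sum(calls) >= 2L
}

#' Genome quality filtering
#'
#' Applies the four genome-retention rules independently and reports every
#' violated rule per genome:
#' \describe{
#'   \item{partial_assembly}{assembly flagged partial in the metadata.}
#'   \item{genus_lt_4}{the genome's genus has fewer than four assemblies in
#'     the input set.  Genus counts are taken once on the full input set,
#'     before any exclusion.}
#'   \item{obs_lt_40}{fewer than 40 distinct "Function;Family" observations
#'     (a genome with exactly 40 is retained).}
#'   \item{tree_placement_fail}{the genome fails the phylogenetic placement
#'     check (only applied when `tree_flags` is supplied).}
#' }
#'
#' @param metadata data.frame as from [read_metadata()].
#' @param obs_counts named integer vector, genome id -> number of distinct
#'   observations; must cover every metadata genome.
#' @param tree_flags optional named logical vector, genome id -> placement ok
#'   (as from [tree_placement_check()]).  Omit to skip the rule.
#' @param min_obs observation threshold, default 40.
#' @param min_genus_assemblies genus size threshold, default 4.
#' @return data.frame with columns `genome_id`, `retained` and `reasons`
#'   (comma-joined rule tokens, empty when retained).
#' @export
filter_genomes <- function(metadata, obs_counts, tree_flags = NULL,
                           min_obs = 40L, min_genus_assemblies = 4L) {
  ids <- metadata$genome_id
  missing <- setdiff(ids, names(obs_counts))
  if (length(missing))
    stop("obs_counts missing genome(s): ", paste(missing, collapse = ", "))
  genus_n <- table(metadata$genus)
  reasons <- lapply(seq_along(ids), function(i) {
    r <- character(0)
    if (metadata$assembly_status[i] == "partial") r <- c(r, "partial_assembly")
    if (genus_n[[metadata$genus[i]]] < min_genus_assemblies) r <- c(r, "genus_lt_4")
    if (obs_counts[[ids[i]]] < min_obs) r <- c(r, "obs_lt_40")
    if (!is.null(tree_flags)) {
      if (is.na(match(ids[i], names(tree_flags))))
        stop("tree_flags missing genome ", ids[i])
      if (!tree_flags[[ids[i]]]) r <- c(r, "tree_placement_fail")
    }
    r
  })
  data.frame(genome_id = ids,
             retained = lengths(reasons) == 0L,
             reasons = vapply(reasons, paste, character(1), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Phylogenetic placement consistency check
#'
#' A genome passes when it sits among its congeners in a reference tree:
#' the smallest enclosing clade holding at least `min_clade` leaves must
#' contain at least `min_congeners` *other* leaves of the same genus.  This
#' formalizes the requirement that a leaf has at least three same-genus
#' species "next by"; the minimal-clade size of 4 is the smallest clade able
#' to hold the leaf plus three congeners.
#'
#' @param tree an `ape::phylo` tree whose tip labels are genome ids;
#'   polytomies allowed.
#' @param metadata data.frame with `genome_id` and `genus` covering every tip.
#' @param min_congeners required number of same-genus neighbours, default 3.
#' @param min_clade minimum clade size defining the neighbourhood, default 4.
#' @return named logical vector over the tree's tips.
#' @export
tree_placement_check <- function(tree, metadata, min_congeners = 3L,
                                 min_clade = 4L) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  tips <- tree$tip.label
  gi <- match(tips, metadata$genome_id)
  if (anyNA(gi))
    stop("tree leaf without metadata: ", tips[which(is.na(gi))[1]])
  genus <- metadata$genus[gi]
  ntip <- length(tips)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # tips under each internal node
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # fill bottom-up: process edges so children come before parents
  ord <- order(tree$edge[, 1], decreasing = TRUE)
  for (e in ord) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    desc[[a]] <- c(desc[[a]], desc[[b]])
  }
  res <- logical(ntip)
  root <- ntip + 1L
  for (i in seq_len(ntip)) {
    node <- parent[i]
    repeat {
      clade <- desc[[node]]
      if (length(clade) >= min_clade || node == root) break
      node <- parent[node]
    }
    res[i] <- sum(genus[clade] == genus[i]) - 1L >= min_congeners
  }
  names(res) <- tips
  res
}
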