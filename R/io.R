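# Canonical token grammars for the observation vocabulary.  A family token is
# a CAZy class prefix plus a family number and an optional subfamily suffix
# ("GH5_5"); a function token is a 4-field EC number whose last field may be
# "-" (incompletely specified activity), or the literal sentinel "unknown".
.family_re <- "^(GH|GT|PL|CE|AA|CBM)[0-9]+(_[0-9]+)?$"
.ec_re     <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

is_family_token <- function(x) grepl(.family_re, x)
is_function_token <- function(x) x == "unknown" | grepl(.ec_re, x)

#' Canonical observation identifier
#'
#' An observation pairs a CAZy family with a molecular function (EC number or
#' the sentinel `"unknown"`).  The canonical string form is `"FAMILY:EC"`,
#' e.g. `"GH1:3.2.1.37"`.  The same EC number in two families yields two
#' distinct observations.
#'
#' @param family CAZy family token(s), e.g. `"GH5"`, `"AA9"`, `"GH5_5"`.
#' @param fun EC token(s) such as `"3.2.1.4"`, or `"unknown"`.
#' @return character vector of canonical observation ids.
#' @examples
#' obs_id("GH1", "3.2.1.37")
#' @export
obs_id <- function(family, fun) {
  bad <- !is_family_token(family)
  if (any(bad)) stop("invalid CAZy family token(s): ", paste(unique(family[bad]), collapse = ", "))
  bad <- !is_function_token(fun)
  if (any(bad)) stop("invalid EC/function token(s): ", paste(unique(fun[bad]), collapse = ", "))
  paste0(family, ":", fun)
}

#' Parse observation identifiers
#'
#' Accepts both orders and both separators seen in the wild
#' (`"GH1:3.2.1.37"`, `"3.2.1.4;GH5"`); always returns the canonical
#' family-first form split into its two components.
#'
#' @param x character vector of observation strings.
#' @return data.frame with columns `family`, `fun`, `id` (canonical form).
#' @export
parse_obs_id <- function(x) {
  parts <- strsplit(x, "[:;]")
  out <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != 2L)
      stop("cannot parse observation id '", x[i], "': expected two ':' or ';' separated tokens")
    fam_at <- which(is_family_token(p))
    if (length(fam_at) != 1L || !is_function_token(p[-fam_at]))
      stop("cannot parse observation id '", x[i],
           "': need exactly one family token and one EC/unknown token")
    c(p[fam_at], p[-fam_at])
  })
  fam <- vapply(out, `[`, character(1), 1L)
  fun <- vapply(out, `[`, character(1), 2L)
  data.frame(family = fam, fun = fun, id = paste0(fam, ":", fun),
             stringsAsFactors = FALSE)
}

#' Strip a subfamily suffix from family tokens
#'
#' Upstream annotation tools emit subfamily-resolved labels such as
#' `"GH5_5"`; by default observation building collapses these onto the parent
#' family (`"GH5"`), so that subfamily splits do not multiply the observation
#' vocabulary.
#'
#' @param family character vector of family tokens.
#' @return family tokens without `_<n>` suffixes.
#' @export
collapse_subfamily <- function(family) sub("_[0-9]+$", "", family)

#' Read a per-protein annotation table
#'
#' The table is tab-separated with a header row and columns `genome_id`,
#' `protein_id`, `family`, `functions`.  `functions` holds one or more EC
#' tokens joined with `";"`, or the sentinel `"unknown"`.  A protein listed
#' with more than one function is an *indecisive* call and is flagged as
#' such; downstream scoring splits its weight across the listed functions.
#'
#' @param path file path of the TSV.
#' @param collapse_subfamilies collapse subfamily tokens (`"GH5_5"`) onto the
#'   parent family (`"GH5"`)?  Default `TRUE`.
#' @return data.frame with columns `genome_id`, `protein_id`, `family`,
#'   `functions` (list column of character vectors) and `indecisive`
#'   (logical, `TRUE` iff more than one function is listed).
#' @export
read_annotations <- function(path, collapse_subfamilies = TRUE) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("genome_id", "protein_id", "family", "functions")
  if (!all(need %in% names(df)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty annotation table: ", path)
  line <- seq_len(nrow(df)) + 1L  # +1 for the header row
  bad <- !is_family_token(df$family)
  if (any(bad))
    stop("malformed family token '", df$family[which(bad)[1]],
         "' on line ", line[which(bad)[1]], " of ", path)
  funs <- strsplit(df$functions, ";", fixed = TRUE)
  for (i in seq_along(funs)) {
    if (length(funs[[i]]) == 0L || !all(is_function_token(funs[[i]])))
      stop("malformed function token(s) '", df$functions[i],
           "' on line ", line[i], " of ", path)
  }
  if (collapse_subfamilies) df$family <- collapse_subfamily(df$family)
  data.frame(genome_id = df$genome_id, protein_id = df$protein_id,
             family = df$family,
             functions = I(funs),
             indecisive = lengths(funs) > 1L,
             stringsAsFactors = FALSE)
}

#' Write an annotation table
#'
#' Inverse of [read_annotations()]; multiple functions are re-joined with
#' `";"`.
#'
#' @param annotations data.frame as returned by [read_annotations()].
#' @param path output file path.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(genome_id = annotations$genome_id,
                   protein_id = annotations$protein_id,
                   family = annotations$family,
                   functions = vapply(annotations$functions, paste,
                                      character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read secretion predictions from three tools
#'
#' Tab-separated table with columns `protein_id`, `tool1`, `tool2`, `tool3`
#' (values 0/1).  Every protein must carry exactly three calls; a missing
#' tool output is an error rather than an implicit negative.
#'
#' @param path file path of the TSV.
#' @return logical matrix, one row per protein (rownames = protein ids),
#'   three columns.
#' @export
read_secretion_calls <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(df) != 4L || names(df)[1] != "protein_id")
    stop("secretion call table must have columns protein_id, tool1, tool2, tool3")
  if (anyDuplicated(df$protein_id))
    stop("duplicate protein_id in secretion calls: ",
         df$protein_id[duplicated(df$protein_id)][1])
  vals <- as.matrix(df[, -1])
  if (any(is.na(vals)) || !all(vals %in% c("0", "1")))
    stop("secretion calls must be 0/1 with exactly 3 call columns per protein")
  m <- vals == "1"
  rownames(m) <- df$protein_id
  colnames(m) <- names(df)[-1]
  m
}

#' Write secretion calls
#' @param calls logical matrix as returned by [read_secretion_calls()].
#' @param path output file path.
#' @export
write_secretion_calls <- function(calls, path) {
  df <- data.frame(protein_id = rownames(calls),
                   tool1 = as.integer(calls[, 1]),
                   tool2 = as.integer(calls[, 2]),
                   tool3 = as.integer(calls[, 3]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a genome metadata / taxonomy table
#'
#' Columns: `genome_id`, `species`, `section`, `genus`, `phylum`,
#' `assembly_status` (`full` or `partial`) and optionally `habitat`.
#' Genome ids must be unique and the taxonomy must be hierarchical (a
#' section belongs to one genus, a genus to one phylum).
#'
#' @param path file path of the TSV.
#' @return data.frame of genome metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("genome_id", "species", "section", "genus", "phylum", "assembly_status")
  if (!all(need %in% names(df)))
    stop("metadata table must have columns ", paste(need, collapse = ", "))
  validate_metadata(df)
  df
}

validate_metadata <- function(df) {
  if (anyDuplicated(df$genome_id))
    stop("duplicate genome_id in metadata: ", df$genome_id[duplicated(df$genome_id)][1])
  if (!all(df$assembly_status %in% c("full", "partial")))
    stop("assembly_status must be 'full' or 'partial'")
  if (anyDuplicated(unique(df[, c("section", "genus")])$section))
    stop("taxonomy not hierarchical: a section maps to more than one genus")
  if (anyDuplicated(unique(df[, c("genus", "phylum")])$genus))
    stop("taxonomy not hierarchical: a genus maps to more than one phylum")
  invisible(df)
}

#' Write a genome metadata table
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output file path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an observation or distance matrix as labeled TSV
#'
#' Binary observation matrices are written as 0/1; square numeric matrices
#' are treated as distance matrices and must be symmetric to within `1e-12`.
#' The first column holds row labels (header `id`).
#'
#' @param m matrix with row and column names: an [build_matrix()] observation
#'   matrix (0/1 integer) or a square numeric distance matrix.
#' @param path output file path.
#' @export
write_matrix <- function(m, path) {
  m <- unclass_obs_matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("refusing to write an empty matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry row and column labels")
  binary <- all(m %in% c(0, 1))
  if (!binary) {
    if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
      stop("non-binary matrices must be square with matching labels (distance matrix)")
    if (max(abs(m - t(m))) > 1e-12)
      stop("distance matrix is asymmetric beyond 1e-12")
  }
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a matrix written by [write_matrix()]
#' @param path file path of the TSV.
#' @return numeric (or 0/1 integer) matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (all(m %in% c(0L, 1L))) storage.mode(m) <- "integer"
  m
}

#' Serialize a dendrogram to Newick
#'
#' Leaf labels are genome ids; branch lengths are chosen ultrametrically so
#' that the cophenetic distance between two leaves in the emitted tree equals
#' the merge height at which they first join (two leaves merged at height
#' `h` sit at depth `h/2` each).
#'
#' @param dendrogram an `hclust` object, e.g. from [complete_linkage()].
#' @param path output file path.
#' @export
write_newick <- function(dendrogram, path) {
  if (!inherits(dendrogram, "hclust")) stop("dendrogram must be an hclust object")
  if (length(dendrogram$labels) < 2L) stop("need at least 2 leaves to serialize")
  if (any(!is.finite(dendrogram$height))) stop("non-finite merge heights")
  phy <- ape::as.phylo(dendrogram)
  ape::write.tree(phy, file = path)
  invisible(path)
}
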