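#' Split genome ids by section
#'
#' @param metadata data.frame with `genome_id` and `section`.
#' @return named list, section -> character vector of genome ids.
#' @export
section_members <- function(metadata) {
  split(metadata$genome_id, metadata$section)
}

#' Enzyme-producer type from the present:absent ratio
#'
#' Sections with a ratio below 1 are weak producers (type III), between one
#' and two (inclusive) medium producers (type II), and above two strong
#' producers (type I).  A section missing nothing (`absent == 0`, infinite
#' ratio) is type I.
#'
#' @param ratio non-negative ratio(s); `Inf` allowed.
#' @return character vector over `c("I", "II", "III")`.
#' @export
assign_profile_type <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio < 0)) stop("ratio must be non-negative")
  ifelse(ratio < 1, "III", ifelse(ratio <= 2, "II", "I"))
}

#' Observations present in every genome
#'
#' Returns the core: observation columns present in all rows of the matrix.
#'
#' @param m 0/1 observation matrix.
#' @return character vector of observation ids.
#' @export
shared_across_all <- function(m) {
  m <- unclass_obs_matrix(m)
  colnames(m)[colSums(m) == nrow(m)]
}

#' Section-level profiling statistics
#'
#' For each section, over its members' rows of the observation matrix:
#' \describe{
#'   \item{total_observations}{distinct observations in the union of the
#'     members.}
#'   \item{total_different_functions}{distinct function tokens in that union;
#'     `"unknown"` counts as one function.}
#'   \item{function_overlap_between_families}{distinct EC numbers occurring
#'     in two or more families within the union (`"unknown"` excluded — it
#'     is not an EC number).}
#'   \item{shared_observations}{observations present in *every* member.}
#'   \item{absent_observations}{observations absent from all members but
#'     present in at least one other genome of the analysis.}
#'   \item{present_absent_ratio}{`total / absent`, `Inf` when nothing is
#'     absent.}
#'   \item{profile_type}{enzyme-producer type from
#'     [assign_profile_type()].}
#' }
#' The global observation universe is the union over all genomes in the
#' matrix, so `total + absent` equals its size for every section.
#'
#' @param m 0/1 observation matrix.
#' @param members named list, section -> genome ids; must cover every row of
#'   `m`, each genome in exactly one section.
#' @return data.frame, one row per section.
#' @export
section_summary <- function(m, members) {
  m <- unclass_obs_matrix(m)
  assigned <- unlist(members, use.names = FALSE)
  if (anyDuplicated(assigned))
    stop("genome assigned to more than one section: ",
         assigned[duplicated(assigned)][1])
  unassigned <- setdiff(rownames(m), assigned)
  if (length(unassigned))
    stop("genome(s) in matrix without a section: ",
         paste(unassigned, collapse = ", "))
  if (length(members) < 2L) stop("need at least 2 sections")
  global <- colnames(m)[colSums(m) >= 1L]
  rows <- lapply(names(members), function(sec) {
    g <- members[[sec]]
    sub <- m[g, , drop = FALSE]
    union_obs <- colnames(sub)[colSums(sub) >= 1L]
    shared_obs <- colnames(sub)[colSums(sub) == length(g)]
    parsed <- if (length(union_obs)) parse_obs_id(union_obs) else
      data.frame(family = character(0), fun = character(0))
    funs <- unique(parsed$fun)
    ec <- parsed[parsed$fun != "unknown", , drop = FALSE]
    fam_per_ec <- tapply(ec$family, ec$fun, function(f) length(unique(f)))
    overlap <- sum(fam_per_ec >= 2)
    absent <- length(setdiff(global, union_obs))
    ratio <- if (absent > 0) length(union_obs) / absent else Inf
    data.frame(section = sec,
               n_species = length(g),
               total_observations = length(union_obs),
               total_different_functions = length(funs),
               function_overlap_between_families = overlap,
               shared_observations = length(shared_obs),
               absent_observations = absent,
               present_absent_ratio = ratio,
               profile_type = assign_profile_type(ratio),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-section presence/absence comparison
#'
#' Classifies each (section, observation) pair as `all_members` (present in
#' every member), `none` (absent from all), or `some_members`, for
#' observations grouped by substrate category (the grouping is user data,
#' not hard-coded biology).
#'
#' @param m 0/1 observation matrix.
#' @param members named list, section -> genome ids.
#' @param observation_groups named list, category -> observation ids; every
#'   id must be a column of `m`.
#' @return data.frame with columns `category`, `observation`, `section`,
#'   `status`.
#' @export
compare_sections <- function(m, members, observation_groups) {
  m <- unclass_obs_matrix(m)
  obs <- unlist(observation_groups, use.names = FALSE)
  unknown <- setdiff(obs, colnames(m))
  if (length(unknown))
    stop("unknown observation(s) in groups: ", paste(unknown, collapse = ", "))
  out <- list()
  for (cat in names(observation_groups)) {
    for (o in observation_groups[[cat]]) {
      for (sec in names(members)) {
        g <- members[[sec]]
        k <- sum(m[g, o])
        status <- if (k == length(g)) "all_members"
                  else if (k == 0L) "none" else "some_members"
        out[[length(out) + 1L]] <- data.frame(
          category = cat, observation = o, section = sec, status = status,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
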