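# Synthetic dataset generator.
#
# The generator states a world with the hierarchical presence/absence
# structure the analysis assumes: a core shared by every genome, nested
# phylum-, genus- and section-level signature blocks (disjoint slices of the
# observation universe, so each section also structurally *lacks* the other
# sections' signatures — shared absence), per-species Bernoulli extras and
# Bernoulli flip noise.  Annotation, secretion-call and taxonomy tables are
# emitted in the package's canonical dialects together with ground truth.

#' Synthetic dataset configuration
#'
#' Defaults describe a small Dikarya-like world: a 295-observation universe
#' with a 24-observation core, two phyla of two genera with two sections of
#' four species each, signature sizes chosen so each genome carries roughly
#' 80-100 observations (within the 40-144 span seen in real genomes).
#'
#' @param n_phyla,genera_per_phylum,sections_per_genus,species_per_section
#'   taxonomy shape (one genome per species).
#' @param universe_size number of distinct observation ids (default 295).
#' @param core_size observations shared by every genome (default 24).
#' @param phylum_signature_size,genus_signature_size,section_signature_size
#'   sizes of the disjoint signature blocks shared by all genomes of a
#'   phylum / genus / section.
#' @param species_extra_rate per-genome inclusion probability for each
#'   unallocated universe observation.
#' @param noise_flip_prob probability of flipping each universe observation
#'   in each genome after the intended set is drawn.
#' @param indecisive_fraction fraction of intended presences realized as a
#'   *pair* of two-way indecisive records (each contributing a half to the
#'   intended observation, with distinct decoy partners that stay below 1).
#' @param nonsecreted_fraction decoy proteins, as a fraction of the genome's
#'   annotated records, carrying real family annotations but failing
#'   secretion votes.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return validated config list of class `epr_config`.
#' @export
synthetic_config <- function(n_phyla = 2L, genera_per_phylum = 2L,
                             sections_per_genus = 2L,
                             species_per_section = 4L,
                             universe_size = 295L, core_size = 24L,
                             phylum_signature_size = 25L,
                             genus_signature_size = 12L,
                             section_signature_size = 20L,
                             species_extra_rate = 0.05,
                             noise_flip_prob = 0.02,
                             indecisive_fraction = 0.1,
                             nonsecreted_fraction = 0.1,
                             seed = 1L) {
  cfg <- list(n_phyla = as.integer(n_phyla),
              genera_per_phylum = as.integer(genera_per_phylum),
              sections_per_genus = as.integer(sections_per_genus),
              species_per_section = as.integer(species_per_section),
              universe_size = as.integer(universe_size),
              core_size = as.integer(core_size),
              phylum_signature_size = as.integer(phylum_signature_size),
              genus_signature_size = as.integer(genus_signature_size),
              section_signature_size = as.integer(section_signature_size),
              species_extra_rate = species_extra_rate,
              noise_flip_prob = noise_flip_prob,
              indecisive_fraction = indecisive_fraction,
              nonsecreted_fraction = nonsecreted_fraction,
              seed = as.integer(seed))
  probs <- c(cfg$species_extra_rate, cfg$noise_flip_prob,
             cfg$indecisive_fraction, cfg$nonsecreted_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  n_gen <- cfg$n_phyla * cfg$genera_per_phylum
  n_sec <- n_gen * cfg$sections_per_genus
  need <- cfg$core_size + cfg$n_phyla * cfg$phylum_signature_size +
    n_gen * cfg$genus_signature_size + n_sec * cfg$section_signature_size
  if (need > cfg$universe_size)
    stop("infeasible sizes: core + signature blocks (", need,
         ") exceed universe_size (", cfg$universe_size, ")")
  if (min(cfg$n_phyla, cfg$genera_per_phylum, cfg$sections_per_genus,
          cfg$species_per_section, cfg$core_size) < 1L)
    stop("taxonomy shape and core_size must be positive")
  class(cfg) <- "epr_config"
  cfg
}

# Build a universe of well-formed Family:EC observation ids.  About 10% of
# the EC tokens are deliberately placed in two families so "function overlap
# between families" is exercised, and ~5% of observations carry the
# "unknown" function.
make_universe <- function(n) {
  prefixes <- c("GH", "GT", "PL", "CE", "AA", "CBM")
  n_fam <- max(12L, ceiling(n / 2))
  fams <- paste0(rep(prefixes, length.out = n_fam),
                 rep(seq_len(ceiling(n_fam / 6)), each = 6)[seq_len(n_fam)])
  n_unknown <- max(1L, round(0.05 * n))
  n_ec <- ceiling((n - n_unknown) / 1.1)
  n_dup <- n - n_unknown - n_ec
  ecs <- sprintf("%d.%d.%d.%d",
                 sample(1:6, n_ec, replace = TRUE),
                 sample(1:9, n_ec, replace = TRUE),
                 sample(1:9, n_ec, replace = TRUE),
                 seq_len(n_ec))
  fam1 <- sample(fams, n_ec, replace = TRUE)
  ids <- obs_id(fam1, ecs)
  if (n_dup > 0) {
    dup_ec <- sample(seq_len(n_ec), n_dup)
    fam2 <- vapply(dup_ec, function(i) sample(setdiff(fams, fam1[i]), 1),
                   character(1))
    ids <- c(ids, obs_id(fam2, ecs[dup_ec]))
  }
  unk_fam <- sample(fams, n_unknown)
  ids <- c(ids, obs_id(unk_fam, rep("unknown", n_unknown)))
  stopifnot(!anyDuplicated(ids), length(ids) == n)
  sample(ids)
}

#' Generate a synthetic dataset
#'
#' Draws the observation universe, plants the hierarchical signature blocks,
#' assembles per-genome intended presence sets (`core + phylum + genus +
#' section signatures + Bernoulli extras`), applies flip noise, and realizes
#' each present observation as 1-3 protein records.  With all corruption
#' rates at zero the pipeline reproduces the intended sets exactly.
#'
#' @param config an `epr_config` from [synthetic_config()].
#' @return list of class `epr_dataset` with `annotations` (data.frame),
#'   `secretion_calls` (logical matrix), `metadata` (data.frame), `truth`
#'   (list: `presence` named list of intended sets, `core`, `signatures`,
#'   `universe`) and `config`.
#' @export
generate <- function(config) {
  if (!inherits(config, "epr_config")) config <- do.call(synthetic_config, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  universe <- make_universe(config$universe_size)
  pool <- universe
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  core <- take(config$core_size)

  habitats <- c("wood", "compost", "dry cereal", "grass", "plant soil",
                "fallen leaves", "dung", "cheese")
  meta <- list(); truth_presence <- list(); sig_of <- list()
  phy_sig <- list(); gen_sig <- list(); sec_sig <- list()
  for (p in seq_len(config$n_phyla)) {
    phy <- sprintf("Phylum%d", p)
    phy_sig[[phy]] <- take(config$phylum_signature_size)
    for (g in seq_len(config$genera_per_phylum)) {
      gen <- sprintf("Genus_P%dG%d", p, g)
      gen_sig[[gen]] <- take(config$genus_signature_size)
      for (s in seq_len(config$sections_per_genus)) {
        sec <- sprintf("P%d.G%d.S%d", p, g, s)
        sec_sig[[sec]] <- take(config$section_signature_size)
        for (k in seq_len(config$species_per_section)) {
          gid <- sprintf("P%dG%dS%dsp%02d", p, g, s, k)
          meta[[gid]] <- data.frame(
            genome_id = gid,
            species = sprintf("%s sp%02d", gen, k),
            section = sec, genus = gen, phylum = phy,
            assembly_status = "full",
            habitat = sample(habitats, 1),
            stringsAsFactors = FALSE)
          sig_of[[gid]] <- c(core, phy_sig[[phy]], gen_sig[[gen]], sec_sig[[sec]])
        }
      }
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  extras_pool <- pool  # unallocated remainder of the universe

  annotations <- list(); call_rows <- list()
  prot_serial <- 0L
  decoy_ec_serial <- 0L
  secreted_votes <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
                          c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  failing_votes <- rbind(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                         c(FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE))
  for (gid in metadata$genome_id) {
    intended <- sig_of[[gid]]
    if (length(extras_pool) && config$species_extra_rate > 0) {
      extra <- extras_pool[stats::runif(length(extras_pool)) < config$species_extra_rate]
      intended <- c(intended, extra)
    }
    truth_presence[[gid]] <- sort(intended, method = "radix")
    observed <- intended
    if (config$noise_flip_prob > 0) {
      flip <- universe[stats::runif(length(universe)) < config$noise_flip_prob]
      observed <- union(setdiff(observed, flip), setdiff(flip, observed))
    }
    observed <- sort(observed, method = "radix")
    parsed <- parse_obs_id(observed)
    recs <- list()
    for (i in seq_along(observed)) {
      fam <- parsed$family[i]; fun <- parsed$fun[i]
      indec <- fun != "unknown" &&
        stats::runif(1) < config$indecisive_fraction
      if (indec) {
        # two indecisive records, each 1/2 for the intended EC paired with a
        # distinct fresh decoy EC in the same family: the intended
        # observation reaches exactly 1, each decoy stays at 1/2
        for (r in 1:2) {
          prot_serial <- prot_serial + 1L
          decoy_ec_serial <- decoy_ec_serial + 1L
          decoy <- sprintf("9.9.9.%d", decoy_ec_serial)
          pid <- sprintf("%s_prot%05d", gid, prot_serial)
          recs[[length(recs) + 1L]] <- list(pid = pid, fam = fam,
                                            funs = c(fun, decoy))
          call_rows[[pid]] <- secreted_votes[sample(4, 1, prob = c(.7, .1, .1, .1)), ]
        }
      } else {
        for (r in seq_len(sample(1:3, 1))) {
          prot_serial <- prot_serial + 1L
          pid <- sprintf("%s_prot%05d", gid, prot_serial)
          recs[[length(recs) + 1L]] <- list(pid = pid, fam = fam, funs = fun)
          call_rows[[pid]] <- secreted_votes[sample(4, 1, prob = c(.7, .1, .1, .1)), ]
        }
      }
    }
    n_decoy <- round(config$nonsecreted_fraction * length(recs))
    if (n_decoy > 0) {
      decoy_obs <- parse_obs_id(sample(universe, n_decoy, replace = TRUE))
      for (j in seq_len(n_decoy)) {
        prot_serial <- prot_serial + 1L
        pid <- sprintf("%s_prot%05d", gid, prot_serial)
        recs[[length(recs) + 1L]] <- list(pid = pid, fam = decoy_obs$family[j],
                                          funs = decoy_obs$fun[j])
        call_rows[[pid]] <- failing_votes[sample(4, 1), ]
      }
    }
    annotations[[gid]] <- data.frame(
      genome_id = gid,
      protein_id = vapply(recs, `[[`, character(1), "pid"),
      family = vapply(recs, `[[`, character(1), "fam"),
      functions = I(lapply(recs, `[[`, "funs")),
      indecisive = vapply(recs, function(r) length(r$funs) > 1L, logical(1)),
      stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, annotations)
  rownames(annotations) <- NULL
  calls <- do.call(rbind, call_rows)
  colnames(calls) <- c("tool1", "tool2", "tool3")

  structure(list(annotations = annotations,
                 secretion_calls = calls,
                 metadata = metadata,
                 truth = list(presence = truth_presence,
                              core = sort(core, method = "radix"),
                              signatures = list(phylum = phy_sig,
                                                genus = gen_sig,
                                                section = sec_sig),
                              universe = universe),
                 config = config),
            class = "epr_dataset")
}

#' @export
print.epr_dataset <- function(x, ...) {
  cat("<epr_dataset> ", nrow(x$metadata), " genomes, ",
      nrow(x$annotations), " protein records, universe of ",
      length(x$truth$universe), " observations (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Ground-truth report tables
#'
#' Materializes the intended (pre-noise) presence sets as a 0/1 matrix and
#' the genome labels, optionally writing both to a directory for use as
#' test oracles.
#'
#' @param dataset an `epr_dataset` from [generate()].
#' @param dir optional output directory; created if missing.
#' @return list with `matrix` (truth presence matrix) and `labels`
#'   (data.frame genome_id/section/genus/phylum), invisibly if written.
#' @export
truth_report <- function(dataset, dir = NULL) {
  tm <- build_matrix(dataset$truth$presence)
  labels <- dataset$metadata[, c("genome_id", "section", "genus", "phylum")]
  out <- list(matrix = tm, labels = labels)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_matrix(tm, file.path(dir, "truth_matrix.tsv"))
    utils::write.table(labels, file.path(dir, "truth_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits `annot.tsv`, `calls.tsv`, `meta.tsv` and a `truth/` subdirectory in
#' the package's canonical TSV dialects.
#'
#' @param dataset an `epr_dataset`.
#' @param dir output directory.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_annotations(dataset$annotations, file.path(dir, "annot.tsv"))
  write_secretion_calls(dataset$secretion_calls, file.path(dir, "calls.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "meta.tsv"))
  truth_report(dataset, file.path(dir, "truth"))
  invisible(dir)
}
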