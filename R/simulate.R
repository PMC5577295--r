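# Seeded synthetic-genus generator.
#
# Emulates the data structure of a barcode survey of a recently radiated
# genus: many closely related species on a star phylogeny, each sampled a
# handful of times, a few haplotypes per species dominated by one frequent
# haplotype, and occasional species pairs sharing a haplotype verbatim
# (which is what drives the minimum interspecific distance to zero and the
# overlap of the intra- and inter-specific distance distributions).
#
# Sequence evolution follows the Kimura 2-parameter substitution process:
# transition rate alpha, each of the two transversion rates beta, ratio
# kappa = alpha/beta, normalised so a branch of length d accumulates d
# expected substitutions per site. Sites evolve independently via the exact
# K80 transition probabilities, so every expectation used in the tests has a
# closed form.

#' Configuration for the synthetic genus generator
#'
#' Defaults emulate an ITS2-like survey of a radiated genus of 47 species
#' sampled 3-6 times each: aligned length 235, expected intraspecific
#' divergence (theta) 0.008 substitutions/site, species branches of 0.010 so
#' that the expected tip-to-tip interspecific K2P distance `2*depth + theta`
#' is 0.028, transition/transversion rate ratio 2, three haplotypes per
#' species with the first dominant, and a 0.1 chance per sister pair of one
#' species copying its dominant haplotype from the other.
#'
#' @param n_species Number of species (>= 1).
#' @param samples_per_species Integer range (e.g. `3:6`) sampled uniformly
#'   per species, or a length-`n_species` vector of exact counts.
#' @param sequence_length Alignment columns.
#' @param interspecific_depth Expected substitutions/site from the genus
#'   ancestor to each species founder.
#' @param intraspecific_theta Expected substitutions/site between two
#'   haplotypes of one species (each haplotype branch has length `theta/2`).
#' @param kappa Transition/transversion rate ratio alpha/beta (> 0).
#' @param haplotype_sharing_prob Probability, per designated sister pair,
#'   that the second species' dominant haplotype is replaced by a verbatim
#'   copy of the first species' dominant haplotype.
#' @param n_sharing_pairs Cap on the number of sister pairs eligible for
#'   sharing (`NULL` = all consecutive pairs).
#' @param n_haplotypes_per_species Haplotypes simulated per species (>= 1).
#' @param dominant_weight Sampling weight of the first haplotype; the rest
#'   share the remainder equally. The first sample of each species is always
#'   assigned the dominant haplotype.
#' @param species_depth_mode `"star"` (all species branches equal `depth`) or
#'   `"varied"` (branch lengths drawn Exponential with mean `depth`).
#' @param gap_rate Per-site probability of replacing a residue by a gap in
#'   each final sequence; 0 by default (used only to exercise pairwise
#'   deletion).
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @return A validated `genus_sim_config`.
#' @export
genus_sim_config <- function(n_species = 47,
                             samples_per_species = 3:6,
                             sequence_length = 235,
                             interspecific_depth = 0.010,
                             intraspecific_theta = 0.008,
                             kappa = 2,
                             haplotype_sharing_prob = 0.1,
                             n_sharing_pairs = NULL,
                             n_haplotypes_per_species = 3,
                             dominant_weight = 0.5,
                             species_depth_mode = c("star", "varied"),
                             gap_rate = 0,
                             seed = 1) {
  species_depth_mode <- match.arg(species_depth_mode)
  cfg <- list(n_species = as.integer(n_species),
              samples_per_species = as.integer(samples_per_species),
              sequence_length = as.integer(sequence_length),
              interspecific_depth = interspecific_depth,
              intraspecific_theta = intraspecific_theta,
              kappa = kappa,
              haplotype_sharing_prob = haplotype_sharing_prob,
              n_sharing_pairs = if (is.null(n_sharing_pairs)) NULL
                                else as.integer(n_sharing_pairs),
              n_haplotypes_per_species = as.integer(n_haplotypes_per_species),
              dominant_weight = dominant_weight,
              species_depth_mode = species_depth_mode,
              gap_rate = gap_rate,
              seed = as.integer(seed))
  ok <- with(cfg, isTRUE(
    n_species >= 1 && sequence_length >= 1 &&
      interspecific_depth >= 0 && intraspecific_theta >= 0 && kappa > 0 &&
      haplotype_sharing_prob >= 0 && haplotype_sharing_prob <= 1 &&
      n_haplotypes_per_species >= 1 &&
      dominant_weight > 0 && dominant_weight <= 1 &&
      gap_rate >= 0 && gap_rate < 1 &&
      length(samples_per_species) >= 1 && all(samples_per_species >= 1)))
  if (!ok) stop("config error: invalid genus simulation parameters")
  class(cfg) <- "genus_sim_config"
  cfg
}

# Exact K80 site-transition probabilities for a branch of length d
# (expected substitutions/site) at transition/transversion ratio kappa.
k80_site_probs <- function(d, kappa) {
  at <- d * kappa / (kappa + 2)  # alpha * t
  bt <- d / (kappa + 2)          # beta * t
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1       # each of the two transversion targets
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv1 = p_tv, tv2 = p_tv)
}

# Transition partner and the two transversion partners per base.
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

evolve_sequence <- function(x, d, kappa) {
  if (d == 0) return(x)
  p <- k80_site_probs(d, kappa)
  event <- sample.int(4, length(x), replace = TRUE, prob = p)
  out <- x
  ts <- event == 2
  out[ts] <- TS_PARTNER[x[ts]]
  for (e in 3:4) {
    idx <- which(event == e)
    if (length(idx)) {
      out[idx] <- vapply(x[idx], function(b) TV_PARTNERS[[b]][e - 2], "")
    }
  }
  out
}

count_subs <- function(a, b) {
  diff <- a != b
  ts <- sum(diff & b == TS_PARTNER[a])
  c(substitutions = sum(diff), transitions = ts,
    transversions = sum(diff) - ts)
}

#' Simulate a labelled synthetic genus
#'
#' Draws a uniform-random ancestral sequence, evolves one founder per species
#' along its species branch, evolves the species' haplotypes from the founder
#' along branches of length `theta/2`, optionally lets a species copy its
#' sister's dominant haplotype verbatim, and assigns samples to haplotypes
#' (first sample pinned to the dominant haplotype, the rest drawn by weight).
#' All randomness flows from `config$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param config A `genus_sim_config`.
#' @return A `synthetic_genus`: list with `alignment` (an `alignment_set`
#'   whose population labels hold the true haplotype), `truth` (species map,
#'   haplotype assignments, sharing events, realized substitution counts per
#'   founder and haplotype branch) and `config`.
#' @export
simulate_genus <- function(config) {
  if (!inherits(config, "genus_sim_config")) {
    stop("config error: use genus_sim_config()")
  }
  cfg <- config
  with_seed(cfg$seed, {
    L <- cfg$sequence_length
    S <- cfg$n_species
    H <- cfg$n_haplotypes_per_species
    ancestor <- sample(PURE_BASES, L, replace = TRUE)
    sp_names <- sprintf("Species_%02d", seq_len(S))
    depths <- switch(cfg$species_depth_mode,
                     star = rep(cfg$interspecific_depth, S),
                     varied = stats::rexp(S, rate = 1 /
                                            max(cfg$interspecific_depth, 1e-12)))
    founders <- lapply(depths, function(d) evolve_sequence(ancestor, d,
                                                           cfg$kappa))
    subs <- list()
    haps <- vector("list", S)
    for (s in seq_len(S)) {
      haps[[s]] <- lapply(seq_len(H), function(h) {
        evolve_sequence(founders[[s]], cfg$intraspecific_theta / 2, cfg$kappa)
      })
      subs[[length(subs) + 1]] <- data.frame(
        branch = paste0(sp_names[s], "_founder"),
        t(count_subs(ancestor, founders[[s]])))
      for (h in seq_len(H)) {
        subs[[length(subs) + 1]] <- data.frame(
          branch = paste0(sp_names[s], "_hap", h),
          t(count_subs(founders[[s]], haps[[s]][[h]])))
      }
    }
    # sister pairs: (1,2), (3,4), ... the second may copy the first's
    # dominant haplotype verbatim
    pairs <- if (S >= 2) seq_len(S %/% 2) else integer(0)
    if (!is.null(cfg$n_sharing_pairs)) {
      pairs <- utils::head(pairs, cfg$n_sharing_pairs)
    }
    sharing <- data.frame(recipient = character(0), donor = character(0))
    for (p in pairs) {
      if (stats::runif(1) < cfg$haplotype_sharing_prob) {
        donor <- 2 * p - 1; recip <- 2 * p
        haps[[recip]][[1]] <- haps[[donor]][[1]]
        sharing <- rbind(sharing, data.frame(recipient = sp_names[recip],
                                             donor = sp_names[donor]))
      }
    }
    # one count per species when lengths match, otherwise a pool of allowed
    # counts sampled uniformly per species
    spp <- cfg$samples_per_species
    n_samples <- if (length(spp) == S) spp
                 else if (length(spp) == 1) rep(spp, S)
                 else sample(spp, S, replace = TRUE)
    w <- if (H == 1) 1 else c(cfg$dominant_weight,
                              rep((1 - cfg$dominant_weight) / (H - 1), H - 1))
    ids <- character(0); species <- character(0); hap_id <- character(0)
    seqs <- list()
    for (s in seq_len(S)) {
      assign_h <- c(1L, if (n_samples[s] > 1) {
        sample.int(H, n_samples[s] - 1, replace = TRUE, prob = w)
      })
      for (k in seq_len(n_samples[s])) {
        id <- sprintf("%s_s%02d", sp_names[s], k)
        x <- haps[[s]][[assign_h[k]]]
        if (cfg$gap_rate > 0) {
          g <- stats::runif(L) < cfg$gap_rate
          x[g] <- GAP_CHAR
        }
        ids <- c(ids, id)
        species <- c(species, sp_names[s])
        hap_id <- c(hap_id, paste0("hap", assign_h[k]))
        seqs[[length(seqs) + 1]] <- x
      }
    }
    mat <- do.call(rbind, seqs)
    rownames(mat) <- ids
    aln <- alignment_set(mat, species = species, population = hap_id)
    truth <- list(
      species_map = stats::setNames(species, ids),
      haplotype_assignments = data.frame(id = ids, species = species,
                                         haplotype = hap_id,
                                         stringsAsFactors = FALSE),
      sharing_events = sharing,
      substitution_counts = do.call(rbind, subs),
      species_depths = stats::setNames(depths, sp_names))
    structure(list(alignment = aln, truth = truth, config = cfg),
              class = "synthetic_genus")
  })
}

#' @export
print.synthetic_genus <- function(x, ...) {
  cat("Synthetic genus:", x$config$n_species, "species,",
      nrow(x$alignment$mat), "sequences x", x$config$sequence_length,
      "sites;", nrow(x$truth$sharing_events), "haplotype-sharing event(s)\n")
  invisible(x)
}

write_config_file <- function(cfg, path) {
  vals <- vapply(cfg, function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, "")
  writeLines(paste0(names(vals), "=", vals), path)
}

#' Write the standard synthetic fixture family
#'
#' Produces, under `out_dir`, the three fixtures the documentation and tests
#' use, each as FASTA + sample map (+ truth tables and the generating config
#' for the simulated ones):
#'
#' * `table5/` — a three-column toy alignment holding the published
#'   three-site states of a focal species' six haplotypes (`CTC`) and its two
#'   closest relatives (`TTC`, `TTG`), with a column-label file mapping the
#'   toy columns to source-alignment positions 141/152/159;
#' * `genus6/` — a 6-species genus in which exactly one sister pair shares a
#'   dominant haplotype verbatim;
#' * `genus47/` — a 47-species genus at survey magnitudes (theta 0.008,
#'   species depth 0.010, hence expected mean interspecific distance 0.028)
#'   with three haplotype-sharing pairs.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed driving the two simulated fixtures.
#' @return Invisibly, a named list of the three fixture directories.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  # (a) printed three-site toy
  t5 <- file.path(out_dir, "table5")
  dir.create(t5, showWarnings = FALSE)
  aln_a <- table5_toy()
  write_alignment(aln_a, file.path(t5, "alignment.fasta"),
                  file.path(t5, "samples.tsv"))
  utils::write.table(data.frame(column = 1:3, label = c(141, 152, 159)),
                     file.path(t5, "columns.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  write_genus <- function(g, dir) {
    dir.create(dir, showWarnings = FALSE)
    write_alignment(g$alignment, file.path(dir, "alignment.fasta"),
                    file.path(dir, "samples.tsv"))
    utils::write.table(g$truth$haplotype_assignments,
                       file.path(dir, "truth_haplotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(g$truth$sharing_events,
                       file.path(dir, "truth_sharing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(g$truth$substitution_counts,
                       file.path(dir, "truth_substitutions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_config_file(g$config, file.path(dir, "config.txt"))
  }

  # (b) small genus with exactly one shared haplotype pair
  cfg_b <- genus_sim_config(n_species = 6, haplotype_sharing_prob = 1,
                            n_sharing_pairs = 1, seed = seed)
  write_genus(simulate_genus(cfg_b), file.path(out_dir, "genus6"))

  # (c) full-size genus at survey magnitudes
  cfg_c <- genus_sim_config(haplotype_sharing_prob = 1, n_sharing_pairs = 3,
                            seed = seed + 1)
  write_genus(simulate_genus(cfg_c), file.path(out_dir, "genus47"))

  invisible(list(table5 = t5,
                 genus6 = file.path(out_dir, "genus6"),
                 genus47 = file.path(out_dir, "genus47")))
}

#' The printed three-site toy alignment
#'
#' Six haplotype representatives of the focal species, all `CTC` at the three
#' diagnostic columns, plus the two closest relatives (`TTC`, `TTG`).
#'
#' @return An `alignment_set` with 8 sequences of 3 columns.
#' @export
table5_toy <- function() {
  seqs <- c(crenulata_Hap_1 = "CTC", crenulata_Hap_2 = "CTC",
            crenulata_Hap_3 = "CTC", crenulata_Hap_4 = "CTC",
            crenulata_Hap_5 = "CTC", crenulata_Hap_6 = "CTC",
            gelida_1 = "TTC", coccinea_1 = "TTG")
  alignment_set(seqs,
                species = c(rep("R_crenulata", 6), "R_gelida", "R_coccinea"))
}
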