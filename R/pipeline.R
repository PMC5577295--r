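# End-to-end pipeline: read -> (region) -> haplotypes -> distances ->
# divergence + gap tests -> identification -> trees + monophyly ->
# diagnostics, each stage writing its artifact, with one machine-readable
# summary at the end.

#' Pipeline configuration
#'
#' Validates and freezes every knob of [run_pipeline()]. The configuration
#' (including the seed) is serialised into the output directory, so any run
#' is reproducible from its own artifacts.
#'
#' @param fasta,samplemap Input paths (aligned FASTA and tab-separated sample
#'   map).
#' @param out_dir Output directory (created if needed).
#' @param region Optional `c(start, end)` columns (1-based inclusive) to
#'   extract before analysis.
#' @param column_labels Optional path to a two-column TSV (`column`, `label`)
#'   relabelling alignment columns in diagnostic reports.
#' @param collapse_scope,gap_policy Passed to [collapse_haplotypes()].
#' @param test_scope `"all_sequences"` (default) computes divergence and gap
#'   tests on every sequence; `"haplotypes"` collapses to one representative
#'   per haplotype first.
#' @param bin_width Histogram bin width for [gap_distributions()].
#' @param id_methods Identification rules to run.
#' @param tree_methods Tree methods to run.
#' @param bootstrap_replicates Bootstrap replicates per tree (0 disables).
#' @param diagnostics_target Species for the diagnostic-SNP stage (`NULL`
#'   picks the species with most samples).
#' @param max_k Largest diagnostic combination size searched.
#' @param seed Integer master seed; stage streams are derived from it.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(fasta, samplemap, out_dir,
                            region = NULL,
                            column_labels = NULL,
                            collapse_scope = "global",
                            gap_policy = "strict",
                            test_scope = c("all_sequences", "haplotypes"),
                            bin_width = 0.005,
                            id_methods = c("best_hit", "nearest_distance"),
                            tree_methods = c("nj", "upgma"),
                            bootstrap_replicates = 0,
                            diagnostics_target = NULL,
                            max_k = 3,
                            seed = 1) {
  test_scope <- match.arg(test_scope)
  for (p in c(fasta, samplemap, column_labels)) {
    if (!file.exists(p)) stop("validation error: input file not found: ", p)
  }
  if (!is.null(region)) {
    if (length(region) != 2 || !is.numeric(region) ||
        region[1] < 1 || region[1] > region[2]) {
      stop("validation error: region must be c(start, end), 1-based inclusive")
    }
  }
  stopifnot(bin_width > 0, bootstrap_replicates >= 0, max_k >= 1)
  id_methods <- match.arg(id_methods, several.ok = TRUE)
  # NULL skips the tree stage (e.g. toy alignments too saturated for K2P)
  tree_methods <- if (is.null(tree_methods)) character(0) else
    match.arg(tree_methods, c("nj", "upgma"), several.ok = TRUE)
  cfg <- list(fasta = fasta, samplemap = samplemap, out_dir = out_dir,
              region = region, column_labels = column_labels,
              collapse_scope = collapse_scope, gap_policy = gap_policy,
              test_scope = test_scope, bin_width = bin_width,
              id_methods = id_methods, tree_methods = tree_methods,
              bootstrap_replicates = as.integer(bootstrap_replicates),
              diagnostics_target = diagnostics_target,
              max_k = as.integer(max_k), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the whole barcode-evaluation pipeline
#'
#' Executes, in order: input reading, optional region extraction, haplotype
#' collapsing, K2P distance matrix, divergence summary with gap distributions
#' and both significance tests, per-query identification with species
#' tabulation for each configured rule, tree building (with optional
#' bootstrap) and monophyly testing for each configured method, and
#' diagnostic-site detection. Every stage writes its artifact under
#' `out_dir` and logs one line; `summary.json` aggregates the headline
#' numbers. A stage failure writes a `FAILED` marker naming the stage and
#' rethrows; earlier artifacts are kept.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("use pipeline_config()")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(...) {
    msg <- paste0(...)
    message("[barcodegap] ", msg)
    cat(msg, "\n", file = file.path(out, "run.log"), append = TRUE)
  }
  stage <- "configuration"
  on_fail <- function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    unlink(file.path(out, "FAILED"))
    serialize_pipeline_config(config, file.path(out, "config.txt"))
    summary <- list(seed = config$seed)

    stage <- "read"
    aln <- read_alignment(config$fasta, config$samplemap)
    log_line("read ", nrow(aln$mat), " sequences x ", ncol(aln$mat),
             " columns, ", length(unique(aln$meta$species)), " species")

    col_labels <- NULL
    if (!is.null(config$column_labels)) {
      cl <- utils::read.delim(config$column_labels)
      col_labels <- as.character(cl$label[order(cl$column)])
    }
    if (!is.null(config$region)) {
      stage <- "extract_region"
      aln <- extract_region(aln, config$region[1], config$region[2])
      if (!is.null(col_labels)) {
        col_labels <- col_labels[config$region[1]:config$region[2]]
      }
      log_line("extracted region ", config$region[1], "..", config$region[2])
    }
    summary$n_sequences <- nrow(aln$mat)
    summary$n_species <- length(unique(aln$meta$species))
    summary$alignment_length <- ncol(aln$mat)

    stage <- "haplotypes"
    ht <- collapse_haplotypes(aln, scope = config$collapse_scope,
                              gap_policy = config$gap_policy)
    write_haplotype_table(ht, file.path(out, "haplotypes.tsv"))
    summary$n_haplotypes <- nrow(ht)
    log_line(nrow(ht), " haplotypes (scope ", config$collapse_scope,
             ", policy ", config$gap_policy, ")")

    stage <- "distances"
    dm <- k2p_matrix(aln)
    write_distance_matrix(dm, file.path(out, "distances.tsv"))
    n_undef <- sum(is.na(dm$distance[upper.tri(dm$distance)]))
    log_line("K2P matrix over ", length(dm$labels), " sequences; ",
             n_undef, " undefined pair(s)")

    stage <- "divergence"
    test_aln <- if (config$test_scope == "haplotypes") {
      haplotype_representatives(aln, scope = config$collapse_scope,
                                gap_policy = config$gap_policy)
    } else aln
    test_dm <- if (config$test_scope == "haplotypes") k2p_matrix(test_aln)
               else dm
    ds <- divergence_summary(test_dm, test_aln)
    write_divergence_summary(ds, file.path(out, "divergence.tsv"))
    gd <- gap_distributions(test_dm, test_aln, bin_width = config$bin_width)
    utils::write.table(gd$histogram, file.path(out, "gap_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tests <- list(
      wilcoxon = wilcoxon_two_sample(gd$intra_values, gd$inter_values),
      median = median_test(gd$intra_values, gd$inter_values))
    summary$divergence <- list(
      mean_interspecific = ds$mean_interspecific,
      theta_prime = ds$theta_prime,
      min_interspecific = ds$min_interspecific,
      mean_intraspecific = ds$mean_intraspecific,
      theta = ds$theta,
      coalescent_depth = ds$coalescent_depth,
      n_undefined_skipped = ds$n_undefined_skipped)
    summary$gap_overlap <- gd$overlap
    summary$tests <- list(
      wilcoxon_p = tests$wilcoxon$p_value,
      wilcoxon_W = tests$wilcoxon$statistic,
      median_p = tests$median$p_value)
    log_line("divergence (scope ", config$test_scope, "): inter ",
             sprintf("%.4f", ds$mean_interspecific), ", intra ",
             sprintf("%.4f", ds$mean_intraspecific), "; wilcoxon p = ",
             format(tests$wilcoxon$p_value), ", median p = ",
             format(tests$median$p_value))

    stage <- "identification"
    summary$identification <- list()
    for (m in config$id_methods) {
      oc <- identify_all(aln, method = m, dm = dm)
      utils::write.table(oc, file.path(out, paste0("outcomes_", m, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab <- tabulate_species(oc)
      write_species_tabulation(tab, file.path(out, paste0("species_", m,
                                                          ".tsv")),
                               method = m)
      summary$identification[[m]] <- list(
        correct_pct = unname(tab$percentages[["CORRECT"]]),
        incorrect_pct = unname(tab$percentages[["INCORRECT"]]),
        ambiguous_pct = unname(tab$percentages[["AMBIGUOUS"]]))
      log_line(m, ": ", tab$counts[["CORRECT"]], "/", tab$n_species,
               " species correct (",
               sprintf("%.1f%%", tab$percentages[["CORRECT"]]), ")")
    }

    stage <- "trees"
    summary$trees <- list()
    for (m in config$tree_methods) {
      tr <- if (config$bootstrap_replicates > 0) {
        bootstrap_support(aln, method = m,
                          replicates = config$bootstrap_replicates,
                          seed = config$seed + 1000 + match(m, c("nj", "upgma")))
      } else if (m == "nj") nj_tree(dm) else upgma_tree(dm)
      ape::write.tree(tr, file.path(out, paste0("tree_", m, ".nwk")))
      mr <- monophyly_report(tr, species_map(aln))
      write_monophyly_report(mr, file.path(out, paste0("monophyly_", m,
                                                       ".tsv")))
      summary$trees[[m]] <- list(discrimination_rate_pct = 100 * mr$rate)
      log_line(m, " tree: discrimination rate ",
               sprintf("%.1f%%", 100 * mr$rate),
               if (config$bootstrap_replicates > 0) {
                 paste0(" (", config$bootstrap_replicates,
                        " bootstrap replicates)")
               } else "")
    }

    stage <- "diagnostics"
    target <- config$diagnostics_target
    if (is.null(target)) {
      target <- names(which.max(table(aln$meta$species)))
    }
    dr <- find_diagnostic_sites(aln, target, column_labels = col_labels)
    write_diagnostic_report(dr, file.path(out, "diagnostic_sites.tsv"))
    cmb <- find_minimal_combinations(aln, target, max_k = config$max_k,
                                     column_labels = col_labels)
    summary$diagnostics <- list(
      target = target,
      single_site_positions = dr$sites$label,
      n_minimal_combinations = length(cmb$combinations),
      status = cmb$status)
    log_line("diagnostics for ", target, ": ", nrow(dr$sites),
             " single-site position(s), ", length(cmb$combinations),
             " minimal combination(s) up to size ", config$max_k)

    stage <- "summary"
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    log_line("summary written")
    invisible(summary)
  }, error = on_fail)
}

serialize_pipeline_config <- function(cfg, path) {
  vals <- vapply(unclass(cfg), function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, "")
  writeLines(paste0(names(vals), "=", vals), path)
}
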