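# Query identification against a reference set: best-hit (a BLAST-style
# surrogate scoring identical aligned columns) and nearest-distance rules,
# each with a three-way outcome:
#   CORRECT   - every optimal reference is from the query's species
#   AMBIGUOUS - the optimal references include the query's species and others
#   INCORRECT - no optimal reference is from the query's species
# The query itself is always excluded as a candidate; its conspecifics
# (including identical sequences) remain, so haplotypes shared between
# species legitimately produce ambiguity.

outcome_of <- function(true_species, hit_species) {
  if (!(true_species %in% hit_species)) "INCORRECT"
  else if (length(hit_species) > 1) "AMBIGUOUS"
  else "CORRECT"
}

#' Identify one query by the nearest-distance rule
#'
#' The hit set is the species of all references attaining the minimal defined
#' K2P distance to the query. Undefined (NA) distances are excluded from the
#' candidate set with a warning.
#'
#' @param query_id Sequence id present in `dm`.
#' @param dm A `k2p_dist` over queries and references together.
#' @param species Named species map or `alignment_set`.
#' @return A `query_outcome`: list with `query_id`, `true_species`, `method`,
#'   `outcome`, `hit_species`, `optimum_value` (the minimal distance).
#' @export
nearest_distance_identify <- function(query_id, dm, species) {
  if (inherits(species, "alignment_set")) species <- species_map(species)
  if (!query_id %in% dm$labels) stop("query '", query_id, "' not in matrix")
  d <- dm$distance[query_id, ]
  d <- d[names(d) != query_id]
  if (anyNA(d)) {
    warning(sum(is.na(d)), " undefined distance(s) excluded for query ",
            query_id)
    d <- d[!is.na(d)]
  }
  if (length(d) == 0) {
    stop("identification error: no defined candidate distance for query ",
         query_id)
  }
  dmin <- min(d)
  hits <- names(d)[d == dmin]
  hit_species <- sort(unique(unname(species[hits])))
  true_species <- unname(species[query_id])
  structure(list(query_id = query_id, true_species = true_species,
                 method = "nearest_distance",
                 outcome = outcome_of(true_species, hit_species),
                 hit_species = hit_species, optimum_value = dmin),
            class = "query_outcome")
}

#' Identify one query by the best-hit rule
#'
#' A BLAST-style surrogate on a fixed alignment: each query/reference pair is
#' scored by the number of aligned columns at which both carry the same
#' non-gap character, and all co-optimal references contribute their species
#' to the hit set. On a shared alignment of near-identical barcodes this
#' ranks references as a BLAST search of full-length queries would.
#'
#' @param query_id Sequence id present in `aln`.
#' @param aln An `alignment_set` holding queries and references.
#' @return A `query_outcome` with `optimum_value` = the best identity score
#'   (number of identical non-gap columns).
#' @export
best_hit_identify <- function(query_id, aln) {
  ids <- aln$meta$id
  if (!query_id %in% ids) stop("query '", query_id, "' not in alignment")
  q <- aln$mat[query_id, ]
  refs <- ids[ids != query_id]
  if (length(refs) == 0) stop("identification error: no references")
  scores <- vapply(refs, function(r) {
    sum(q == aln$mat[r, ] & q != GAP_CHAR)
  }, numeric(1))
  smax <- max(scores)
  hits <- refs[scores == smax]
  species <- species_map(aln)
  hit_species <- sort(unique(unname(species[hits])))
  true_species <- unname(species[query_id])
  structure(list(query_id = query_id, true_species = true_species,
                 method = "best_hit",
                 outcome = outcome_of(true_species, hit_species),
                 hit_species = hit_species, optimum_value = smax),
            class = "query_outcome")
}

#' @export
print.query_outcome <- function(x, ...) {
  cat(x$query_id, " (", x$true_species, ") by ", x$method, ": ", x$outcome,
      " [hits: ", paste(x$hit_species, collapse = ", "),
      " at ", format(x$optimum_value), "]\n", sep = "")
  invisible(x)
}

#' Identify every sequence in an alignment
#'
#' Runs the chosen rule with each sequence in turn as the query and the rest
#' as references (self-queries against the full database, as in a barcode
#' library evaluation).
#'
#' @param aln An `alignment_set`.
#' @param method `"nearest_distance"` or `"best_hit"`.
#' @param dm Optional precomputed `k2p_dist` (recomputed when missing;
#'   only used by the nearest-distance rule).
#' @return data.frame with one row per query: `query_id`, `true_species`,
#'   `method`, `outcome`, `hit_species` (comma-separated), `optimum_value`.
#' @export
identify_all <- function(aln, method = c("nearest_distance", "best_hit"),
                         dm = NULL) {
  method <- match.arg(method)
  if (method == "nearest_distance" && is.null(dm)) dm <- k2p_matrix(aln)
  rows <- lapply(aln$meta$id, function(q) {
    o <- if (method == "nearest_distance") {
      nearest_distance_identify(q, dm, species_map(aln))
    } else {
      best_hit_identify(q, aln)
    }
    data.frame(query_id = o$query_id, true_species = o$true_species,
               method = o$method, outcome = o$outcome,
               hit_species = paste(o$hit_species, collapse = ","),
               optimum_value = o$optimum_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Species-level tabulation of identification outcomes
#'
#' Reduces per-query outcomes to one label per species — INCORRECT if any of
#' the species' queries is INCORRECT, else AMBIGUOUS if any is AMBIGUOUS,
#' else CORRECT — and tabulates counts and percentages over species (not
#' over queries).
#'
#' @param outcomes data.frame as returned by [identify_all()] (columns
#'   `query_id`, `true_species`, `outcome`).
#' @return A `species_tabulation`: `per_species` data.frame, `counts`,
#'   `percentages`, `n_samples`, `n_species`.
#' @export
tabulate_species <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("tabulation error: no outcomes")
  species <- unique(outcomes$true_species)
  lab <- vapply(species, function(s) {
    oc <- outcomes$outcome[outcomes$true_species == s]
    if (length(oc) == 0) stop("tabulation error: species without queries: ", s)
    if (any(oc == "INCORRECT")) "INCORRECT"
    else if (any(oc == "AMBIGUOUS")) "AMBIGUOUS"
    else "CORRECT"
  }, "")
  per <- data.frame(species = species, outcome = unname(lab),
                    n_queries = as.vector(table(factor(outcomes$true_species,
                                                       levels = species))),
                    stringsAsFactors = FALSE)
  counts <- c(CORRECT = sum(lab == "CORRECT"),
              INCORRECT = sum(lab == "INCORRECT"),
              AMBIGUOUS = sum(lab == "AMBIGUOUS"))
  structure(list(per_species = per, counts = counts,
                 percentages = 100 * counts / length(species),
                 n_samples = nrow(outcomes), n_species = length(species)),
            class = "species_tabulation")
}

#' @export
print.species_tabulation <- function(x, ...) {
  cat("Species-level identification over", x$n_species, "species (",
      x$n_samples, "queries):\n")
  for (k in names(x$counts)) {
    cat(sprintf("  %-9s %d (%.1f%%)\n", k, x$counts[[k]],
                x$percentages[[k]]))
  }
  invisible(x)
}

#' Write a species tabulation as TSV
#'
#' One summary row in the shape of an authentication-efficiency table:
#' marker, method, sample and species counts, and the three outcome classes
#' with percentages over species.
#'
#' @param x A `species_tabulation`.
#' @param path Output path.
#' @param marker,method Strings identifying the barcode and the rule.
#' @return Invisibly, `x`.
#' @export
write_species_tabulation <- function(x, path, marker = "barcode",
                                     method = "nearest_distance") {
  cell <- function(k) sprintf("%d (%.1f%%)", x$counts[[k]],
                              x$percentages[[k]])
  df <- data.frame(marker = marker, method = method,
                   n_samples = x$n_samples, n_species = x$n_species,
                   correct = cell("CORRECT"), incorrect = cell("INCORRECT"),
                   ambiguous = cell("AMBIGUOUS"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
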