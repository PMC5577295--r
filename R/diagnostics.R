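# Species-diagnostic nucleotide positions ("stable SNPs") and minimal
# multi-site signatures.
#
# A column is a candidate only when the target species is fixed for a single
# unambiguous base there (any gap or ambiguity code within the target
# disqualifies the column). A non-target sequence carrying a gap or ambiguity
# code at a candidate column is treated as possibly matching the target
# state, so such columns (or combinations touching them for that sequence)
# are conservatively rejected: a signature must not misfire on incomplete
# data.

target_fixed_columns <- function(aln, target) {
  in_target <- aln$meta$species == target
  if (!any(in_target)) stop("mapping error: unknown species '", target, "'")
  tmat <- aln$mat[in_target, , drop = FALSE]
  fixed <- logical(ncol(tmat))
  state <- character(ncol(tmat))
  for (k in seq_len(ncol(tmat))) {
    u <- unique(tmat[, k])
    if (length(u) == 1 && u %in% PURE_BASES) {
      fixed[k] <- TRUE
      state[k] <- u
    }
  }
  list(in_target = in_target, fixed = which(fixed), state = state[fixed])
}

# compatibility[m, c]: could non-target sequence m match the target state at
# candidate column c? TRUE when identical, or when m carries a gap/ambiguity.
compatibility_matrix <- function(aln, tf) {
  omat <- aln$mat[!tf$in_target, tf$fixed, drop = FALSE]
  comp <- matrix(FALSE, nrow(omat), ncol(omat))
  for (c in seq_len(ncol(omat))) {
    comp[, c] <- omat[, c] == tf$state[c] | !(omat[, c] %in% PURE_BASES)
  }
  comp
}

#' Single-site diagnostic positions for a species
#'
#' Scans every alignment column for a "stable" diagnostic site: the target
#' species is fixed for one unambiguous base that no other sequence in the
#' alignment can carry. Positions are reported 1-based relative to the
#' analysed alignment (optionally relabelled through `column_labels`, e.g. to
#' coordinates of a source alignment).
#'
#' @param aln An `alignment_set`.
#' @param target Species label to diagnose.
#' @param column_labels Optional vector (length = alignment length) of
#'   user-facing position labels.
#' @return A `diagnostic_report` with `sites`: data.frame `position`,
#'   `label`, `target_state`, `other_states` (comma-separated states seen in
#'   non-target sequences at that column).
#' @export
find_diagnostic_sites <- function(aln, target, column_labels = NULL) {
  tf <- target_fixed_columns(aln, target)
  comp <- compatibility_matrix(aln, tf)
  diag_cols <- tf$fixed[colSums(comp) == 0]
  diag_state <- tf$state[colSums(comp) == 0]
  labels <- position_labels(aln, column_labels)
  omat <- aln$mat[!tf$in_target, , drop = FALSE]
  others <- vapply(diag_cols, function(k) {
    paste(sort(unique(omat[, k])), collapse = ",")
  }, "")
  sites <- data.frame(position = diag_cols,
                      label = labels[diag_cols],
                      target_state = diag_state,
                      other_states = others,
                      stringsAsFactors = FALSE)
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(target = target, sites = sites,
                 n_target = sum(tf$in_target),
                 n_candidate_columns = length(tf$fixed),
                 alignment_length = alignment_length(aln)),
            class = "diagnostic_report")
}

position_labels <- function(aln, column_labels) {
  if (is.null(column_labels)) return(as.character(seq_len(alignment_length(aln))))
  if (length(column_labels) != alignment_length(aln)) {
    stop("column_labels must have one entry per alignment column")
  }
  as.character(column_labels)
}

#' Minimal multi-site diagnostic signatures for a species
#'
#' Exhaustively searches subsets (up to `max_k` positions) of the columns at
#' which the target species is fixed, returning every minimal subset whose
#' joint state vector occurs in all target sequences and can occur in no
#' other sequence. Subsets are visited in (size, lexicographic-position)
#' order, and no reported combination contains another as a subset.
#'
#' @param aln An `alignment_set`.
#' @param target Species label.
#' @param max_k Largest combination size searched (default 3).
#' @param column_labels Optional position relabelling (see
#'   [find_diagnostic_sites()]).
#' @param search_ceiling Guard on the number of candidate subsets
#'   (`sum over k of choose(n_candidates, k)`); the search refuses to start
#'   above it.
#' @return A `diagnostic_report` with `combinations`: list of data.frames
#'   (`position`, `label`, `target_state`), and `status` (`"found"` or
#'   `"none_found"`).
#' @export
find_minimal_combinations <- function(aln, target, max_k = 3,
                                      column_labels = NULL,
                                      search_ceiling = 2e5) {
  if (max_k < 1) stop("max_k must be >= 1")
  tf <- target_fixed_columns(aln, target)
  comp_all <- compatibility_matrix(aln, tf)
  # a column every non-target could match excludes nobody, so it can never
  # occur in a minimal signature: prune before the exhaustive search
  informative <- colSums(!comp_all) > 0
  if (nrow(comp_all) == 0) informative <- rep(TRUE, ncol(comp_all))
  tf$fixed <- tf$fixed[informative]
  tf$state <- tf$state[informative]
  nc <- length(tf$fixed)
  n_subsets <- sum(choose(nc, seq_len(min(max_k, nc))))
  if (n_subsets > search_ceiling) {
    stop("combinatorial guard: ", nc, " candidate columns give ",
         format(n_subsets, big.mark = ","), " subsets up to size ", max_k,
         " (> ceiling ", format(search_ceiling, big.mark = ","),
         "); raise search_ceiling or lower max_k")
  }
  comp <- comp_all[, informative, drop = FALSE]
  labels <- position_labels(aln, column_labels)
  found <- list()       # integer vectors of candidate-column indices
  for (k in seq_len(min(max_k, nc))) {
    subsets <- utils::combn(nc, k, simplify = FALSE)
    for (s in subsets) {
      if (any(vapply(found, function(f) all(f %in% s), logical(1)))) next
      works <- nrow(comp) == 0 ||
        !any(apply(comp[, s, drop = FALSE], 1, all))
      if (works) found[[length(found) + 1]] <- s
    }
  }
  combos <- lapply(found, function(s) {
    data.frame(position = tf$fixed[s],
               label = labels[tf$fixed[s]],
               target_state = tf$state[s],
               stringsAsFactors = FALSE)
  })
  structure(list(target = target, combinations = combos,
                 status = if (length(combos)) "found" else "none_found",
                 max_k = max_k,
                 n_target = sum(tf$in_target),
                 n_candidate_columns = nc,
                 alignment_length = alignment_length(aln)),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat("Diagnostic report for species '", x$target, "' (", x$n_target,
      " member(s))\n", sep = "")
  if (!is.null(x$sites)) {
    if (nrow(x$sites) == 0) {
      cat("  no single-site diagnostics\n")
    } else {
      cat("  single-site diagnostics at position(s): ",
          paste(x$sites$label, collapse = ", "), "\n", sep = "")
    }
  }
  if (!is.null(x$combinations)) {
    if (x$status == "none_found") {
      cat("  no diagnostic combination up to size ", x$max_k, "\n", sep = "")
    } else {
      for (cb in x$combinations) {
        cat("  combination: positions ", paste(cb$label, collapse = "+"),
            " states ", paste(cb$target_state, collapse = ""), "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' Write single-site diagnostics as TSV
#' @param x A `diagnostic_report` from [find_diagnostic_sites()].
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_diagnostic_report <- function(x, path) {
  utils::write.table(x$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' State matrix at selected positions for all species
#'
#' A compact dump, one row per haplotype per species, of the states at the
#' given alignment positions — the usual way a multi-site signature is
#' presented.
#'
#' @param aln An `alignment_set`.
#' @param positions Integer vector of 1-based alignment columns.
#' @param column_labels Optional position relabelling.
#' @return data.frame with `species`, `n_members` and one column per position.
#' @export
signature_state_matrix <- function(aln, positions, column_labels = NULL) {
  labels <- position_labels(aln, column_labels)
  ht <- collapse_haplotypes(aln, scope = "per_species")
  states <- do.call(rbind, lapply(strsplit(ht$sequence, ""), function(s) {
    s[positions]
  }))
  colnames(states) <- paste0("pos_", labels[positions])
  cbind(data.frame(species = ht$species, haplotype = ht$haplotype_id,
                   n_members = ht$n_members, stringsAsFactors = FALSE),
        as.data.frame(states, stringsAsFactors = FALSE))
}
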