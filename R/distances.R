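# Kimura 2-parameter distances with pairwise deletion.
#
# Sites where either sequence carries a gap or an IUPAC ambiguity code are
# excluded from the pair's comparison (pairwise deletion). With P the
# proportion of transitions (A<->G, C<->T) and Q the proportion of
# transversions among the comparable sites,
#   d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q).
# The distance is undefined (NA) when either logarithm argument is
# non-positive or when no comparable sites remain; undefined entries are
# propagated, never imputed or saturated.

encode_pure <- function(chars) {
  # A=1, C=2, G=3, T=4; everything else (gap, ambiguity) NA
  m <- match(chars, PURE_BASES)
  m
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' @param seq_a,seq_b Aligned sequences: strings or character vectors of equal
#'   length.
#' @return A list with `distance` (numeric, `NA` when undefined),
#'   `comparable_sites`, `transitions`, `transversions`, `P`, `Q`.
#' @examples
#' k2p_distance(strrep("A", 90), paste0(strrep("A", 80), strrep("G", 10)))
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(toupper(seq_a), "")[[1]] else toupper(seq_a)
  b <- if (length(seq_b) == 1L) strsplit(toupper(seq_b), "")[[1]] else toupper(seq_b)
  if (length(a) != length(b)) {
    stop("length error: sequences have lengths ", length(a), " and ", length(b))
  }
  ea <- encode_pure(a)
  eb <- encode_pure(b)
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  if (n == 0) {
    return(list(distance = NA_real_, comparable_sites = 0L,
                transitions = 0L, transversions = 0L,
                P = NA_real_, Q = NA_real_))
  }
  diffs <- abs(ea[ok] - eb[ok])
  ts <- sum(diffs == 2L)   # A<->G and C<->T are exactly 2 apart in the coding
  tv <- sum(diffs != 0L) - ts
  P <- ts / n
  Q <- tv / n
  d <- k2p_from_pq(P, Q)
  list(distance = d, comparable_sites = as.integer(n),
       transitions = as.integer(ts), transversions = as.integer(tv),
       P = P, Q = Q)
}

k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- w1 * NA_real_                    # keeps dim/dimnames for matrices
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d[ok] <- -0.5 * log(w1[ok]) - 0.25 * log(w2[ok]) + 0  # +0 drops IEEE -0
  d
}

#' All pairwise K2P distances of an alignment
#'
#' Computes the full symmetric matrix of Kimura 2-parameter distances under
#' pairwise deletion, together with the number of comparable sites per pair.
#' Implemented through base-indicator cross-products so the cost is a handful
#' of matrix multiplications rather than an explicit pair loop.
#'
#' @param aln An `alignment_set` with at least 2 sequences.
#' @return An object of class `k2p_dist`: list with `labels`, `distance`
#'   (symmetric numeric matrix, `NA` marking undefined pairs, zero diagonal),
#'   `sites` (symmetric integer matrix of comparable sites).
#' @export
k2p_matrix <- function(aln) {
  mat <- aln$mat
  if (nrow(mat) < 2) stop("need at least 2 sequences")
  ind <- lapply(PURE_BASES, function(b) (mat == b) * 1)
  names(ind) <- PURE_BASES
  cross <- function(x, y) ind[[x]] %*% t(ind[[y]])
  comparable <- matrix(0, nrow(mat), nrow(mat))
  matches <- matrix(0, nrow(mat), nrow(mat))
  for (x in PURE_BASES) {
    for (y in PURE_BASES) {
      cc <- cross(x, y)
      comparable <- comparable + cc
      if (x == y) matches <- matches + cc
    }
  }
  transitions <- cross("A", "G") + cross("G", "A") +
    cross("C", "T") + cross("T", "C")
  transversions <- comparable - matches - transitions
  P <- ifelse(comparable > 0, transitions / comparable, NA_real_)
  Q <- ifelse(comparable > 0, transversions / comparable, NA_real_)
  d <- k2p_from_pq(P, Q)
  d[comparable == 0] <- NA_real_
  diag(d) <- 0
  labels <- aln$meta$id
  dimnames(d) <- list(labels, labels)
  sites <- comparable
  storage.mode(sites) <- "integer"
  dimnames(sites) <- dimnames(d)
  structure(list(labels = labels, distance = d, sites = sites),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  nu <- sum(is.na(x$distance[upper.tri(x$distance)]))
  cat("K2P distance matrix:", n, "sequences,", n * (n - 1) / 2, "pairs;",
      nu, "undefined\n")
  invisible(x)
}

#' Build a `k2p_dist` from a plain matrix
#'
#' Wraps an externally supplied symmetric distance matrix (for example from a
#' simulation oracle) in the container the tree and divergence stages accept.
#'
#' @param m Symmetric numeric matrix with dimnames; `NA` marks undefined pairs.
#' @param sites Optional matrix of comparable-site counts (defaults to 0).
#' @return A `k2p_dist`.
#' @export
as_k2p_dist <- function(m, sites = NULL) {
  if (is.null(rownames(m))) stop("matrix needs dimnames")
  if (!isTRUE(all.equal(m, t(m)))) stop("matrix must be symmetric")
  if (is.null(sites)) {
    sites <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  structure(list(labels = rownames(m), distance = m, sites = sites),
            class = "k2p_dist")
}

#' Write / read a distance matrix as square TSV
#'
#' Undefined entries are serialised as `NA`. The first column holds the
#' sequence ids.
#'
#' @param dm A `k2p_dist`.
#' @param path File path.
#' @return `write_distance_matrix` returns `dm` invisibly;
#'   `read_distance_matrix` returns a `k2p_dist` (with zero site counts).
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(id = dm$labels, dm$distance, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dm)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  diag(m) <- 0
  as_k2p_dist(m)
}

#' Write a lower-triangle PHYLIP-style distance file
#'
#' @param dm A `k2p_dist`.
#' @param path File path.
#' @param digits Significant digits written.
#' @return Invisibly, `dm`.
#' @export
write_phylip_lower <- function(dm, path, digits = 6) {
  n <- length(dm$labels)
  lines <- character(n + 1)
  lines[1] <- as.character(n)
  for (i in seq_len(n)) {
    vals <- if (i > 1) {
      formatC(dm$distance[i, seq_len(i - 1)], digits = digits, format = "f")
    } else character(0)
    lines[i + 1] <- paste(c(format(dm$labels[i], width = 10), vals),
                          collapse = "  ")
  }
  writeLines(lines, path)
  invisible(dm)
}
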