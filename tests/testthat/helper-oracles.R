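# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately re-derives its quantity by a different route than the
# package (per-site classification loops, exhaustive enumeration, graph
# traversal) so agreement is informative.

rand_alignment <- function(n, L, species = NULL, gap_prob = 0,
                           ambig_prob = 0) {
  pool <- c("A", "C", "G", "T")
  mat <- matrix(sample(pool, n * L, replace = TRUE), n, L)
  if (gap_prob > 0) mat[runif(n * L) < gap_prob] <- "-"
  if (ambig_prob > 0) mat[runif(n * L) < ambig_prob] <- "N"
  rownames(mat) <- sprintf("s%03d", seq_len(n))
  if (is.null(species)) species <- rep("sp", n)
  alignment_set(mat, species = species)
}

# Naive per-site K2P: classify every aligned site pair explicitly.
naive_k2p <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  pure <- c("A", "C", "G", "T")
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(a)) {
    x <- a[k]; y <- b[k]
    if (!(x %in% pure) || !(y %in% pure)) next
    n <- n + 1L
    if (x == y) next
    pair <- paste(sort(c(x, y)), collapse = "")
    if (pair %in% c("AG", "CT")) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0) return(list(distance = NA_real_, comparable_sites = 0L))
  P <- ts / n; Q <- tv / n
  d <- if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) NA_real_ else
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  list(distance = d, comparable_sites = n)
}

# Exhaustive two-sided rank-sum p by enumerating every group assignment.
enum_wilcoxon_p <- function(a, b) {
  n_a <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n_a)])
  sums <- combn(length(r), n_a, function(ix) sum(r[ix]))
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more probable than observed.
enum_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monophyly oracle: remove each edge in turn and collect the tip labels
# reachable from its child endpoint by breadth-first search over the
# remaining edges; a species is monophyletic (unrooted sense) iff some such
# side equals the species' tips or their complement.
oracle_monophyly_unrooted <- function(phy, species) {
  tips <- phy$tip.label
  n <- length(tips)
  sides <- lapply(seq_len(nrow(phy$edge)), function(e) {
    adj <- phy$edge[-e, , drop = FALSE]
    reach <- phy$edge[e, 2]
    repeat {
      nxt <- unique(c(adj[adj[, 1] %in% reach, 2],
                      adj[adj[, 2] %in% reach, 1]))
      nxt <- setdiff(nxt, reach)
      if (length(nxt) == 0) break
      reach <- c(reach, nxt)
    }
    sort(tips[reach[reach <= n]])
  })
  vapply(unique(species[tips]), function(s) {
    set <- sort(tips[species[tips] == s])
    comp <- sort(setdiff(tips, set))
    any(vapply(sides, function(x) identical(x, set) || identical(x, comp),
               logical(1)))
  }, logical(1))
}

# Path-length (patristic) distances of a phylo, by independent route.
tree_distances <- function(phy) {
  m <- ape::cophenetic.phylo(phy)
  m[order(rownames(m)), order(colnames(m))]
}

expect_same_distances <- function(phy, dmat, tol = 1e-8) {
  got <- tree_distances(phy)
  want <- dmat[order(rownames(dmat)), order(colnames(dmat))]
  expect_equal(got, want, tolerance = tol)
}
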