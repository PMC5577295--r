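# Distance trees (neighbor joining, UPGMA), column bootstrap and species
# monophyly tests. Trees are `ape` "phylo" objects throughout, so the usual
# plotting and Newick I/O tooling applies.

check_tree_matrix <- function(dm) {
  d <- dm$distance
  if (length(dm$labels) < 2) stop("need at least 2 labels")
  bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("matrix error: undefined distance between '",
         dm$labels[bad[1, 1]], "' and '", dm$labels[bad[1, 2]], "'")
  }
  check_newick_safe(dm$labels)
  d
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a K2P distance matrix
#'
#' Saitou-Nei neighbor joining using the Studier-Keppler criterion
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j`. Ties in the minimal `Q` are broken
#' deterministically by the lowest pair in the current cluster order, so the
#' result is platform independent. The returned tree is unrooted (basal
#' trifurcation). Negative branch lengths are clamped to zero; the total
#' clamped amount is stored in `attr(tree, "negative_branch_adjustment")`.
#'
#' @param dm A `k2p_dist` with at least 3 labels and no undefined entries.
#' @return An unrooted `phylo` tree with branch lengths in
#'   substitutions/site.
#' @export
nj_tree <- function(dm) {
  d <- check_tree_matrix(dm)
  n <- length(dm$labels)
  if (n < 3) stop("neighbor joining needs at least 3 labels")
  node <- dm$labels           # newick fragment per active cluster
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  while (length(node) > 3) {
    r <- length(node)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin & upper.tri(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- clamp(0.5 * d[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    lj <- clamp(d[i, j] - (0.5 * d[i, j] + (R[i] - R[j]) / (2 * (r - 2))))
    merged <- paste0("(", node[i], ":", fmt_bl(li), ",",
                     node[j], ":", fmt_bl(lj), ")")
    dn <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    node <- c(node[keep], merged)
  }
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- paste0("(", node[1], ":", fmt_bl(la), ",",
                node[2], ":", fmt_bl(lb), ",",
                node[3], ":", fmt_bl(lc), ");")
  phy <- ape::read.tree(text = nwk)
  attr(phy, "negative_branch_adjustment") <- clamped
  phy
}

#' UPGMA tree from a K2P distance matrix
#'
#' Average-linkage agglomeration: at each step the closest pair of clusters is
#' merged (ties broken by lowest pair in cluster order) at a node of height
#' half the merge distance, so the result is a rooted ultrametric tree.
#'
#' @param dm A `k2p_dist` with at least 2 labels and no undefined entries.
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  d <- check_tree_matrix(dm)
  node <- dm$labels
  height <- rep(0, length(node))
  size <- rep(1L, length(node))
  clamped <- 0
  while (length(node) > 1) {
    r <- length(node)
    dd <- d
    diag(dd) <- Inf
    dmin <- min(dd)
    cand <- which(dd == dmin & upper.tri(dd), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    h <- dmin / 2
    bi <- h - height[i]; bj <- h - height[j]
    if (bi < 0) { clamped <- clamped - bi; bi <- 0 }
    if (bj < 0) { clamped <- clamped - bj; bj <- 0 }
    merged <- paste0("(", node[i], ":", fmt_bl(bi), ",",
                     node[j], ":", fmt_bl(bj), ")")
    dn <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    node <- c(node[keep], merged)
    height <- c(height[keep], max(h, height[i], height[j]))
    size <- c(size[keep], size[i] + size[j])
  }
  phy <- ape::read.tree(text = paste0(node[1], ";"))
  attr(phy, "negative_branch_adjustment") <- clamped
  phy
}

# Tip-label set below each edge (the edge's child side). Returns a list with
# one character vector per edge row of phy$edge, plus per-node descendant sets.
edge_tip_sets <- function(phy) {
  phy2 <- ape::reorder.phylo(phy, "postorder")
  n <- length(phy2$tip.label)
  sets <- vector("list", n + phy2$Nnode)
  for (i in seq_len(n)) sets[[i]] <- phy2$tip.label[i]
  edge_sets <- vector("list", nrow(phy2$edge))
  for (e in seq_len(nrow(phy2$edge))) {
    p <- phy2$edge[e, 1]; ch <- phy2$edge[e, 2]
    edge_sets[[e]] <- sets[[ch]]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  list(edge_sets = edge_sets, node_sets = sets, phy = phy2, n_tips = n)
}

# Canonical key of the bipartition an edge induces: the side NOT containing
# the lexicographically smallest tip label, sorted and joined.
split_key <- function(side, all_labels, ref) {
  if (ref %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = "\r")
}

# Keys of all non-trivial bipartitions (internal edges) of a tree.
internal_split_keys <- function(phy) {
  es <- edge_tip_sets(phy)
  all_labels <- phy$tip.label
  ref <- min(all_labels)
  sizes <- lengths(es$edge_sets)
  keep <- sizes >= 2 & sizes <= length(all_labels) - 2
  vapply(es$edge_sets[keep], split_key, "", all_labels = all_labels, ref = ref)
}

#' Bootstrap support for a distance tree
#'
#' Nonparametric bootstrap over alignment columns: columns are resampled with
#' replacement, the K2P matrix and tree are rebuilt for each replicate, and
#' each internal edge of the original tree is annotated with the percentage
#' of replicates whose tree contains the same bipartition. Replicates whose
#' resampled matrix contains an undefined distance are skipped and counted
#' (`attr(tree, "bootstrap_skipped")`); supports are percentages of the
#' completed replicates.
#'
#' @param aln An `alignment_set`.
#' @param method `"nj"` or `"upgma"`.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed; the same seed and input give identical
#'   supports.
#' @return The tree built from the full alignment, with `node.label` holding
#'   bootstrap percentages for internal nodes (root and trifurcation base
#'   labelled `""`).
#' @export
bootstrap_support <- function(aln, method = c("nj", "upgma"),
                              replicates = 100, seed = NULL) {
  method <- match.arg(method)
  if (replicates < 1) stop("replicates must be >= 1")
  build <- if (method == "nj") nj_tree else upgma_tree
  dm <- k2p_matrix(aln)
  phy <- build(dm)
  ref_keys <- internal_split_keys(phy)
  counts <- stats::setNames(numeric(length(ref_keys)), ref_keys)
  L <- alignment_length(aln)
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- alignment_set(aln$mat[, cols, drop = FALSE],
                               species = aln$meta$species,
                               population = aln$meta$population)
      rep_dm <- k2p_matrix(rep_aln)
      if (any(is.na(rep_dm$distance[upper.tri(rep_dm$distance)]))) {
        skipped <- skipped + 1L
        next
      }
      rep_keys <- internal_split_keys(build(rep_dm))
      hit <- ref_keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  if (skipped > 0) {
    warning(skipped, " bootstrap replicate(s) skipped (undefined distances)")
  }
  done <- replicates - skipped
  support <- if (done > 0) 100 * counts / done else counts * NA_real_
  # attach supports to internal nodes via each node's parent-edge bipartition
  es <- edge_tip_sets(phy)
  n <- es$n_tips
  labels <- rep("", phy$Nnode)
  all_labels <- phy$tip.label
  ref <- min(all_labels)
  for (e in seq_len(nrow(es$phy$edge))) {
    ch <- es$phy$edge[e, 2]
    if (ch > n) {
      key <- split_key(es$edge_sets[[e]], all_labels, ref)
      if (key %in% ref_keys) {
        labels[ch - n] <- formatC(support[[key]], format = "g")
      }
    }
  }
  phy$node.label <- labels
  attr(phy, "bootstrap_skipped") <- skipped
  attr(phy, "bootstrap_replicates") <- replicates
  phy
}

#' Species monophyly report from a tree
#'
#' For a rooted tree a species is monophyletic when some clade contains
#' exactly the species' tips; for an unrooted tree, when some edge bipartition
#' has the species' tips alone on one side. The overall discrimination rate
#' is the fraction of counted species that are monophyletic; singleton
#' species (which cannot fail the test) are counted as successes by default
#' or excluded with `singleton_policy = "exclude"`.
#'
#' @param tree A `phylo` tree.
#' @param species Named character vector mapping tip labels to species, or an
#'   `alignment_set`.
#' @param singleton_policy `"count_as_success"` or `"exclude"`.
#' @return A `monophyly_report`: data.frame `per_species` (species, n_tips,
#'   monophyletic), `rate`, `n_counted`, `singleton_policy`, `rooted`.
#' @export
monophyly_report <- function(tree, species,
                             singleton_policy = c("count_as_success",
                                                  "exclude")) {
  singleton_policy <- match.arg(singleton_policy)
  if (inherits(species, "alignment_set")) species <- species_map(species)
  tips <- tree$tip.label
  sp <- species[tips]
  if (any(is.na(sp))) {
    stop("mapping error: tip(s) without species: ",
         paste(tips[is.na(sp)], collapse = ", "))
  }
  rooted <- ape::is.rooted(tree)
  es <- edge_tip_sets(tree)
  key_of <- function(s) paste(sort(s), collapse = "\r")
  if (rooted) {
    clade_keys <- unique(vapply(es$node_sets, key_of, ""))
  } else {
    sides <- es$edge_sets
    comp <- lapply(sides, function(s) setdiff(tips, s))
    clade_keys <- unique(vapply(c(sides, comp), key_of, ""))
  }
  species_levels <- unique(sp)
  per <- data.frame(species = species_levels,
                    n_tips = as.vector(table(factor(sp,
                                                    levels = species_levels))),
                    stringsAsFactors = FALSE)
  per$monophyletic <- vapply(species_levels, function(s) {
    key_of(tips[sp == s]) %in% clade_keys
  }, logical(1))
  counted <- if (singleton_policy == "exclude") per$n_tips > 1 else
    rep(TRUE, nrow(per))
  rate <- if (any(counted)) mean(per$monophyletic[counted]) else NA_real_
  structure(list(per_species = per, rate = rate, n_counted = sum(counted),
                 singleton_policy = singleton_policy, rooted = rooted),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat("Monophyly report (", if (x$rooted) "rooted" else "unrooted",
      " tree): ", sum(x$per_species$monophyletic), "/", nrow(x$per_species),
      " species monophyletic; discrimination rate ",
      sprintf("%.1f%%", 100 * x$rate),
      " over ", x$n_counted, " counted species (singletons: ",
      x$singleton_policy, ")\n", sep = "")
  invisible(x)
}

#' Write a monophyly report as TSV
#' @param x A `monophyly_report`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_monophyly_report <- function(x, path) {
  utils::write.table(x$per_species, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}
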