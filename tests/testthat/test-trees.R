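test_that("NJ resolves the worked 4-taxon additive matrix exactly", {
  labels <- LETTERS[1:4]
  m <- matrix(0, 4, 4, dimnames = list(labels, labels))
  m["A", "B"] <- 3; m["A", "C"] <- 5; m["A", "D"] <- 6
  m["B", "C"] <- 6; m["B", "D"] <- 7; m["C", "D"] <- 7
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  tr <- nj_tree(as_k2p_dist(m))
  expect_false(ape::is.rooted(tr))
  # split AB|CD present
  mono <- monophyly_report(tr, setNames(c("P", "P", "Q", "Q"), labels))
  expect_true(all(mono$per_species$monophyletic))
  # path distances reproduce the matrix (A:1, B:2, internal:1, C:3, D:4)
  expect_same_distances(tr, m)
  bl <- setNames(tr$edge.length, tr$edge[, 2])
  tip_bl <- bl[as.character(seq_len(4))]
  expect_equal(unname(tip_bl[order(tr$tip.label)]), c(1, 2, 3, 4))
})

test_that("NJ solves the 3-taxon star in closed form and rejects bad input", {
  labels <- c("A", "B", "C")
  m <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, dimnames = list(labels, labels))
  tr <- nj_tree(as_k2p_dist(m))
  expect_same_distances(tr, m)
  expect_equal(sort(tr$edge.length), c(0, 2, 3))

  zero <- matrix(0, 3, 3, dimnames = list(labels, labels))
  expect_equal(sum(nj_tree(as_k2p_dist(zero))$edge.length), 0)

  m_na <- m; m_na["A", "C"] <- m_na["C", "A"] <- NA
  expect_error(nj_tree(as_k2p_dist(m_na)), "matrix error.*A.*C")
  expect_error(nj_tree(as_k2p_dist(m[1:2, 1:2])), "at least 3")
})

test_that("NJ exactly recovers random additive matrices (<= 12 tips)", {
  set.seed(71)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    m <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(as_k2p_dist(m))
    expect_same_distances(tr, m)
  }
})

test_that("UPGMA agglomerates the worked example and 2-taxon case", {
  labels <- c("A", "B", "C")
  m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, dimnames = list(labels, labels))
  tr <- upgma_tree(as_k2p_dist(m))
  expect_true(ape::is.rooted(tr))
  expect_same_distances(tr, m)           # ((A:1,B:1):1,C:2)
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 2))

  m2 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  expect_equal(ape::write.tree(upgma_tree(as_k2p_dist(m2))),
               "(A:0.25,B:0.25);")
})

test_that("UPGMA exactly recovers ultrametric matrices and is ultrametric", {
  set.seed(72)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    ref <- ape::rcoal(n)
    m <- ape::cophenetic.phylo(ref)
    tr <- upgma_tree(as_k2p_dist(m))
    expect_same_distances(tr, m)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(max(depths) - min(depths), 1e-9)
  }
})

test_that("Newick round-trip preserves topology, lengths and supports", {
  set.seed(73)
  g <- simulate_genus(genus_sim_config(n_species = 4, seed = 2))
  tr <- bootstrap_support(g$alignment, "nj", replicates = 20, seed = 99)
  path <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  o <- order(back$edge[, 2]); o2 <- order(tr$edge[, 2])
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
})

test_that("bootstrap supports are deterministic, bounded, and 100 for a
           clean zero/large split", {
  # two clusters: identical within, 10/40 transversions between
  mix <- paste0(strrep("T", 10), strrep("A", 30))
  aln <- alignment_set(
    c(a1 = strrep("A", 40), a2 = strrep("A", 40), a3 = strrep("A", 40),
      b1 = mix, b2 = mix, b3 = mix),
    species = rep(c("A", "B"), each = 3))
  tr1 <- bootstrap_support(aln, "nj", replicates = 50, seed = 7)
  tr2 <- bootstrap_support(aln, "nj", replicates = 50, seed = 7)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  sup <- suppressWarnings(as.numeric(tr1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(100 %in% sup)  # the A|B split survives every resample

  g <- simulate_genus(genus_sim_config(n_species = 5, seed = 31))
  tru <- bootstrap_support(g$alignment, "upgma", replicates = 25, seed = 3)
  supu <- suppressWarnings(as.numeric(tru$node.label))
  supu <- supu[!is.na(supu)]
  expect_true(all(supu >= 0 & supu <= 100))
})

test_that("monophyly: worked splits on rooted and unrooted trees", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  rep1 <- monophyly_report(ape::unroot(tr),
                           setNames(c("A", "A", "B", "B"),
                                    c("a1", "a2", "b1", "b2")))
  expect_true(all(rep1$per_species$monophyletic))

  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  rep2 <- monophyly_report(tr2, setNames(c("A", "B", "A", "B"),
                                         c("a1", "b1", "a2", "b2")))
  expect_false(any(rep2$per_species$monophyletic))
  expect_equal(rep2$rate, 0)
  expect_error(monophyly_report(tr2, setNames("A", "a1")), "mapping error")
})

test_that("monophyly agrees with the exhaustive bipartition oracle on all
           unrooted 5-tip topologies and random trees up to 8 tips", {
  skip_if_not_installed("phangorn")
  tips <- c("a1", "a2", "b1", "b2", "b3")
  sp <- setNames(c("A", "A", "B", "B", "B"), tips)
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = tips)
  for (k in seq_along(all5)) {
    tr <- all5[[k]]  # [[ ]] re-attaches tip labels on a multiPhylo
    tr$edge.length <- rep(1, nrow(tr$edge))
    got <- monophyly_report(tr, sp)
    want <- oracle_monophyly_unrooted(tr, sp)
    expect_equal(setNames(got$per_species$monophyletic,
                          got$per_species$species),
                 want[got$per_species$species])
  }
  set.seed(74)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    tr <- ape::unroot(ape::rtree(n))
    sp <- setNames(sample(c("A", "B", "C"), n, replace = TRUE),
                   tr$tip.label)
    if (length(unique(sp)) < 2) next
    got <- monophyly_report(tr, sp)
    want <- oracle_monophyly_unrooted(tr, sp)
    expect_equal(setNames(got$per_species$monophyletic,
                          got$per_species$species),
                 want[got$per_species$species])
  }
})

test_that("singleton policy changes the discrimination denominator", {
  tr <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,c1:1):1);")
  sp <- setNames(c("A", "B", "A", "C"), c("a1", "b1", "a2", "c1"))
  inc <- monophyly_report(tr, sp, singleton_policy = "count_as_success")
  exc <- monophyly_report(tr, sp, singleton_policy = "exclude")
  expect_equal(inc$n_counted, 3)  # B and C singletons counted as successes
  expect_equal(inc$rate, 2 / 3)
  expect_equal(exc$n_counted, 1)  # only A has >= 2 tips
  expect_equal(exc$rate, 0)
})
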