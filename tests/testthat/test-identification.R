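three_species_toy <- function() {
  # references from three species at the printed three-site states, plus a
  # second query haplotype of the focal species
  alignment_set(c(cren_hap1 = "CTC", cren_hap2 = "CTC",
                  gelida = "TTC", coccinea = "TTG"),
                species = c("crenulata", "crenulata", "gelida", "coccinea"))
}

test_that("nearest distance: conspecific zero-distance hit is CORRECT", {
  aln <- three_species_toy()
  dm <- k2p_matrix(aln)
  o <- nearest_distance_identify("cren_hap2", dm, species_map(aln))
  expect_equal(o$outcome, "CORRECT")
  expect_equal(o$hit_species, "crenulata")
  expect_equal(o$optimum_value, 0)
})

test_that("nearest distance: equidistant heterospecific tie is AMBIGUOUS", {
  aln <- alignment_set(c(q = "AAAA", x1 = "AAAA", y1 = "AAAA", z = "TTTT"),
                       species = c("X", "X", "Y", "Z"))
  # the q-z pair is all-transversion saturated: excluded with a warning
  expect_warning(
    o <- nearest_distance_identify("q", k2p_matrix(aln), species_map(aln)),
    "undefined")
  expect_equal(o$outcome, "AMBIGUOUS")
  expect_setequal(o$hit_species, c("X", "Y"))
})

test_that("nearest distance: absent conspecific reference gives INCORRECT", {
  aln <- alignment_set(c(q = "TTG", gelida = "TTC", cren = "CTC"),
                       species = c("coccinea", "gelida", "crenulata"))
  o <- nearest_distance_identify("q", k2p_matrix(aln), species_map(aln))
  expect_equal(o$outcome, "INCORRECT")
  expect_equal(o$hit_species, "gelida")  # 1 difference vs 2
})

test_that("nearest distance: all-undefined candidates raise an error", {
  aln <- alignment_set(c(q = "AA--", r = "--AA", s = "--AA"),
                       species = c("X", "Y", "Y"))
  dm <- k2p_matrix(aln)
  expect_error(suppressWarnings(
    nearest_distance_identify("q", dm, species_map(aln))),
    "identification error")
})

test_that("best hit: identity scoring and the three-way rule", {
  aln <- three_species_toy()
  o <- best_hit_identify("cren_hap1", aln)
  expect_equal(o$outcome, "CORRECT")
  expect_equal(o$optimum_value, 3)

  # query identical to references from two species -> AMBIGUOUS
  aln2 <- alignment_set(c(q = "ACGT", x = "ACGT", y = "ACGT"),
                        species = c("X", "X", "Y"))
  expect_equal(best_hit_identify("q", aln2)$outcome, "AMBIGUOUS")

  # more identical columns with a heterospecific (9) than any conspecific (8)
  aln3 <- alignment_set(
    c(q = "AAAAAAAAAA", self = "AAAAAAAACC", other = "AAAAAAAAAC"),
    species = c("X", "X", "Y"))
  o3 <- best_hit_identify("q", aln3)
  expect_equal(o3$outcome, "INCORRECT")
  expect_equal(o3$optimum_value, 9)
})

test_that("outcome trichotomy holds for every query on a simulated genus", {
  g <- simulate_genus(genus_sim_config(n_species = 6, seed = 21))
  aln <- g$alignment
  dm <- k2p_matrix(aln)
  for (m in c("nearest_distance", "best_hit")) {
    oc <- identify_all(aln, method = m, dm = dm)
    expect_true(all(oc$outcome %in% c("CORRECT", "AMBIGUOUS", "INCORRECT")))
    expect_true(all(nzchar(oc$hit_species)))
  }
})

test_that("unique-per-species sequences make every best-hit query CORRECT
           only when a conspecific duplicate exists; self is excluded", {
  # every sequence unique but each species has two near-identical members
  aln <- alignment_set(c(x1 = "AAAAAAAA", x2 = "AAAAAAAC",
                         y1 = "TTTTTTTT", y2 = "TTTTTTTC"),
                       species = c("X", "X", "Y", "Y"))
  oc <- identify_all(aln, method = "best_hit")
  expect_true(all(oc$outcome == "CORRECT"))
  # the query never hits itself: optimum below the self-score of 8
  expect_true(all(oc$optimum_value == 7))
})

test_that("best-hit equals nearest distance under p-distance on gap-free
           data, and nearly always under K2P", {
  g <- simulate_genus(genus_sim_config(n_species = 8, seed = 5))
  aln <- g$alignment
  # identity score is L minus Hamming distance, so best-hit must match
  # nearest-distance run on the p-distance matrix exactly
  L <- alignment_length(aln)
  h <- matrix(0, nrow(aln$mat), nrow(aln$mat),
              dimnames = list(aln$meta$id, aln$meta$id))
  for (i in seq_len(nrow(h))) for (j in seq_len(nrow(h))) {
    h[i, j] <- sum(aln$mat[i, ] != aln$mat[j, ]) / L
  }
  pm <- as_k2p_dist(h)
  b <- identify_all(aln, method = "best_hit")
  p_out <- vapply(aln$meta$id, function(q)
    nearest_distance_identify(q, pm, species_map(aln))$outcome, "")
  expect_equal(b$outcome, unname(p_out))
  # K2P ranks nearly identically (it can split ties of equal Hamming
  # distance but different transition/transversion make-up)
  a <- identify_all(aln, method = "nearest_distance")
  expect_gte(mean(a$outcome == b$outcome), 0.9)
})

test_that("species tabulation applies INCORRECT > AMBIGUOUS > CORRECT", {
  oc <- data.frame(
    query_id = sprintf("q%d", 1:6),
    true_species = c("A", "A", "B", "B", "C", "C"),
    outcome = c("CORRECT", "AMBIGUOUS", "CORRECT", "CORRECT", "AMBIGUOUS",
                "INCORRECT"))
  tab <- tabulate_species(oc)
  per <- setNames(tab$per_species$outcome, tab$per_species$species)
  expect_equal(per[["A"]], "AMBIGUOUS")
  expect_equal(per[["B"]], "CORRECT")
  expect_equal(per[["C"]], "INCORRECT")
  expect_equal(sum(tab$counts), 3)
  expect_equal(sum(tab$percentages), 100)
})

test_that("tabulation reproduces a 47-species 27/0/20 split structurally", {
  # 27 all-correct species, 20 species containing an ambiguous query
  oc <- do.call(rbind, lapply(1:47, function(s) {
    n <- 3
    out <- rep("CORRECT", n)
    if (s > 27) out[2] <- "AMBIGUOUS"
    data.frame(query_id = sprintf("s%02d_q%d", s, 1:n),
               true_species = sprintf("sp%02d", s), outcome = out)
  }))
  tab <- tabulate_species(oc)
  expect_equal(unname(tab$counts["CORRECT"]), 27)
  expect_equal(unname(tab$counts["AMBIGUOUS"]), 20)
  expect_equal(unname(tab$counts["INCORRECT"]), 0)
  expect_equal(unname(tab$percentages["CORRECT"]), 100 * 27 / 47)
  expect_equal(unname(tab$percentages["AMBIGUOUS"]), 100 * 20 / 47)
})

test_that("correct-identification percentage does not rise with sharing", {
  probs <- c(0, 0.5, 1)
  seeds <- 1:4
  mean_correct <- sapply(probs, function(p) {
    mean(sapply(seeds, function(s) {
      g <- simulate_genus(genus_sim_config(n_species = 10,
                                           haplotype_sharing_prob = p,
                                           seed = 100 + s))
      oc <- identify_all(g$alignment, method = "nearest_distance")
      tabulate_species(oc)$percentages[["CORRECT"]]
    }))
  })
  expect_true(all(diff(mean_correct) <= 1e-9))
})
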