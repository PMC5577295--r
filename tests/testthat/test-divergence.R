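make_dm <- function(vals, labels) {
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (nm in names(vals)) {
    ij <- strsplit(nm, "|", fixed = TRUE)[[1]]
    m[ij[1], ij[2]] <- m[ij[2], ij[1]] <- vals[[nm]]
  }
  as_k2p_dist(m)
}

test_that("six parameters match hand enumeration on a 2x2 design", {
  labels <- c("a1", "a2", "b1", "b2")
  sp <- setNames(c("A", "A", "B", "B"), labels)
  dm <- make_dm(list("a1|a2" = 0.01, "b1|b2" = 0.03,
                     "a1|b1" = 0.1, "a1|b2" = 0.1,
                     "a2|b1" = 0.1, "a2|b2" = 0.1), labels)
  ds <- divergence_summary(dm, sp)
  expect_equal(ds$mean_intraspecific, 0.02)
  expect_equal(ds$theta, 0.02)
  expect_equal(ds$coalescent_depth, 0.03)
  expect_equal(ds$mean_interspecific, 0.1)
  expect_equal(ds$theta_prime, 0.1)
  expect_equal(ds$min_interspecific, 0.1)
  expect_equal(ds$n_inter_pairs + ds$n_intra_pairs + ds$n_undefined_skipped,
               choose(4, 2))
})

test_that("identical sequences give all-zero parameters", {
  aln <- alignment_set(c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT"),
                       species = c("A", "A", "B"))
  ds <- divergence_summary(k2p_matrix(aln), aln)
  for (f in c("mean_interspecific", "theta_prime", "min_interspecific",
              "mean_intraspecific", "theta", "coalescent_depth")) {
    expect_equal(ds[[f]], 0)
  }
})

test_that("singleton species are excluded from intraspecific statistics", {
  labels <- c("a1", "b1", "b2")
  sp <- setNames(c("A", "B", "B"), labels)
  dm <- make_dm(list("a1|b1" = 0.05, "a1|b2" = 0.05, "b1|b2" = 0),
                labels)
  ds <- divergence_summary(dm, sp)
  expect_equal(ds$n_intra_pairs, 1)
  expect_equal(ds$mean_intraspecific, 0)
  # all-singleton input: intraspecific parameters unavailable, not zero
  dm2 <- make_dm(list("a1|b1" = 0.05), c("a1", "b1"))
  ds2 <- divergence_summary(dm2, setNames(c("A", "B"), c("a1", "b1")))
  expect_true(is.na(ds2$mean_intraspecific))
  expect_true(is.na(ds2$coalescent_depth))
  expect_equal(ds2$n_intra_pairs, 0)
})

test_that("summary is invariant under sequence relabelling/reordering", {
  set.seed(12)
  g <- simulate_genus(genus_sim_config(n_species = 5, seed = 9))
  aln <- g$alignment
  dm <- k2p_matrix(aln)
  perm <- sample(nrow(aln$mat))
  aln2 <- alignment_set(aln$mat[perm, ], aln$meta$species[perm],
                        aln$meta$population[perm])
  ds1 <- divergence_summary(dm, aln)
  ds2 <- divergence_summary(k2p_matrix(aln2), aln2)
  for (f in c("mean_interspecific", "theta_prime", "min_interspecific",
              "mean_intraspecific", "theta", "coalescent_depth")) {
    expect_equal(ds1[[f]], ds2[[f]], tolerance = 1e-12)
  }
})

test_that("theta prime definitions: species-pair mean vs pooled pairs", {
  labels <- c("a1", "a2", "b1", "c1")
  sp <- setNames(c("A", "A", "B", "C"), labels)
  dm <- make_dm(list("a1|a2" = 0, "a1|b1" = 0.1, "a2|b1" = 0.3,
                     "a1|c1" = 0.2, "a2|c1" = 0.2, "b1|c1" = 0.5), labels)
  ds_pair <- divergence_summary(dm, sp, theta_prime = "species_pair_mean")
  # pair means: A-B 0.2, A-C 0.2, B-C 0.5 -> 0.3
  expect_equal(ds_pair$theta_prime, 0.3)
  ds_all <- divergence_summary(dm, sp, theta_prime = "all_pairs")
  expect_equal(ds_all$theta_prime, mean(c(0.1, 0.3, 0.2, 0.2, 0.5)))
  expect_equal(ds_all$theta_prime, ds_all$mean_interspecific)
})

test_that("gap histograms bin correctly and flag overlap", {
  labels <- c("a1", "a2", "b1")
  sp <- setNames(c("A", "A", "B"), labels)
  dm <- make_dm(list("a1|a2" = 0.0, "a1|b1" = 0.1, "a2|b1" = 0.1), labels)
  gd <- gap_distributions(dm, sp, bin_width = 0.05)
  expect_equal(gd$histogram$intra, c(1, 0, 0))
  expect_equal(gd$histogram$inter, c(0, 0, 2))
  expect_false(gd$overlap)
  expect_equal(sum(gd$histogram$intra), length(gd$intra_values))

  dm2 <- make_dm(list("a1|a2" = 0.02, "a1|b1" = 0.01, "a2|b1" = 0.03), labels)
  expect_true(gap_distributions(dm2, sp)$overlap)
  expect_error(gap_distributions(dm, sp, bin_width = 0), "parameter error")
})

test_that("empty interspecific list yields an empty side, no error", {
  labels <- c("a1", "a2")
  dm <- make_dm(list("a1|a2" = 0.01), labels)
  gd <- gap_distributions(dm, setNames(c("A", "A"), labels))
  expect_equal(length(gd$inter_values), 0)
  expect_false(gd$overlap)
})

test_that("exact Wilcoxon p matches exhaustive enumeration (all n <= 10)", {
  set.seed(33)
  for (n_a in 1:5) for (n_b in n_a:(10 - n_a)) {
    if (n_b < 1) next
    # ties made likely by drawing from a small integer pool
    a <- sample(1:4, n_a, replace = TRUE)
    b <- sample(1:4, n_b, replace = TRUE)
    got <- wilcoxon_two_sample(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, enum_wilcoxon_p(a, b), tolerance = 1e-12,
                 info = paste("n_a", n_a, "n_b", n_b))
  }
})

test_that("worked rank-sum examples: 2/6, 2/10, degenerate ties", {
  expect_equal(wilcoxon_two_sample(c(1, 2), c(3, 4))$p_value, 2 / 6,
               tolerance = 1e-12)
  expect_equal(wilcoxon_two_sample(c(1, 2, 3), c(4, 5))$p_value, 2 / 10,
               tolerance = 1e-12)
  expect_equal(wilcoxon_two_sample(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_error(wilcoxon_two_sample(numeric(0), 1), "parameter error")
})

test_that("exact Wilcoxon agrees with wilcox.test on untied data", {
  set.seed(8)
  for (i in 1:10) {
    a <- runif(5); b <- runif(6)
    got <- wilcoxon_two_sample(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(got$p_value, ref, tolerance = 1e-9)
  }
})

test_that("normal approximation stays close to the exact p at n = 30 + 30", {
  set.seed(21)
  for (i in 1:20) {
    a <- sample(seq(0, 1, by = 0.05), 30, replace = TRUE)
    b <- sample(seq(0.2, 1.2, by = 0.05), 30, replace = TRUE)
    exact <- wilcoxon_two_sample(a, b, exact_limit = Inf)
    approx <- wilcoxon_two_sample(a, b, exact_limit = 1)
    expect_equal(exact$method, "exact")
    expect_equal(approx$method, "normal_approximation")
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  }
})

test_that("median test matches hypergeometric enumeration on small groups", {
  got <- median_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$method, "fisher_exact")
  expect_equal(unname(got$table), rbind(c(0, 3), c(3, 0)))
  expect_equal(got$p_value, 0.1, tolerance = 1e-12)
  expect_equal(got$p_value, enum_fisher_p(got$table), tolerance = 1e-12)

  expect_equal(median_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 1)
  expect_equal(median_test(1, 2)$method, "fisher_exact")
  expect_error(median_test(numeric(0), 1), "parameter error")

  set.seed(13)
  for (i in 1:20) {
    a <- sample(1:6, sample(2:5, 1), replace = TRUE)
    b <- sample(1:6, sample(2:5, 1), replace = TRUE)
    got <- median_test(a, b)
    if (got$method == "fisher_exact") {
      expect_equal(got$p_value, enum_fisher_p(got$table), tolerance = 1e-9)
    }
  }
})

test_that("median test switches to chi-square for large balanced groups", {
  set.seed(14)
  a <- rnorm(60); b <- rnorm(60, 1)
  got <- median_test(a, b)
  expect_equal(got$method, "chi_square")
  ref <- stats::chisq.test(got$table, correct = FALSE)
  expect_equal(got$p_value, ref$p.value)
})
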