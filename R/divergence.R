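# Inter/intra-specific divergence parameters, barcoding-gap distributions and
# the two significance tests comparing them.

pairwise_table <- function(dm, species) {
  labels <- dm$labels
  sp <- species[labels]
  if (any(is.na(sp))) {
    stop("mapping error: label(s) without species: ",
         paste(labels[is.na(sp)], collapse = ", "))
  }
  idx <- which(upper.tri(dm$distance), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             sp_i = sp[idx[, 1]], sp_j = sp[idx[, 2]],
             d = dm$distance[idx],
             intra = sp[idx[, 1]] == sp[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Six-parameter divergence summary
#'
#' Computes, from a labelled K2P distance matrix, the standard barcoding-gap
#' characterisation: three interspecific parameters (mean interspecific
#' distance, theta prime, minimum interspecific distance) and three
#' intraspecific parameters (mean intraspecific distance, theta, coalescent
#' depth).
#'
#' * mean interspecific: mean (and sd) over all defined between-species pairs;
#' * theta prime: by default the unweighted mean over species pairs of the
#'   mean between-species distance (`"species_pair_mean"`); the literal
#'   all-pairs pooled mean is available as `theta_prime = "all_pairs"`;
#' * minimum interspecific: smallest defined between-species distance;
#' * mean intraspecific: mean (and sd) over all defined within-species pairs;
#' * theta: unweighted mean over species with at least two sampled sequences
#'   of the species' mean intraspecific distance;
#' * coalescent depth: maximum defined within-species distance.
#'
#' Undefined (NA) pairs are skipped and counted, never imputed. When every
#' species is a singleton the intraspecific parameters are reported as `NA`
#' (not zero).
#'
#' @param dm A `k2p_dist`.
#' @param species Named character vector mapping sequence ids to species, or
#'   an `alignment_set` (its species map is used).
#' @param theta_prime `"species_pair_mean"` (default) or `"all_pairs"`.
#' @return An object of class `divergence_summary`.
#' @export
divergence_summary <- function(dm, species,
                               theta_prime = c("species_pair_mean",
                                               "all_pairs")) {
  theta_prime <- match.arg(theta_prime)
  if (inherits(species, "alignment_set")) species <- species_map(species)
  pt <- pairwise_table(dm, species)
  defined <- !is.na(pt$d)
  inter <- pt[defined & !pt$intra, ]
  intra <- pt[defined & pt$intra, ]

  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  mean_inter <- if (nrow(inter)) mean(inter$d) else NA_real_
  sd_inter <- if (nrow(inter)) sd0(inter$d) else NA_real_
  min_inter <- if (nrow(inter)) min(inter$d) else NA_real_

  if (theta_prime == "species_pair_mean" && nrow(inter)) {
    key <- paste(pmin(inter$sp_i, inter$sp_j), pmax(inter$sp_i, inter$sp_j),
                 sep = "\r")
    pair_means <- tapply(inter$d, key, mean)
    tp <- mean(pair_means)
    sd_tp <- sd0(as.vector(pair_means))
  } else if (nrow(inter)) {
    tp <- mean_inter
    sd_tp <- sd_inter
  } else {
    tp <- sd_tp <- NA_real_
  }

  if (nrow(intra)) {
    mean_intra <- mean(intra$d)
    sd_intra <- sd0(intra$d)
    depth <- max(intra$d)
    sp_means <- tapply(intra$d, intra$sp_i, mean)
    theta <- mean(sp_means)
    sd_theta <- sd0(as.vector(sp_means))
  } else {
    mean_intra <- sd_intra <- depth <- theta <- sd_theta <- NA_real_
  }

  structure(list(
    mean_interspecific = mean_inter, sd_interspecific = sd_inter,
    theta_prime = tp, sd_theta_prime = sd_tp,
    min_interspecific = min_inter,
    mean_intraspecific = mean_intra, sd_intraspecific = sd_intra,
    theta = theta, sd_theta = sd_theta,
    coalescent_depth = depth,
    n_inter_pairs = nrow(inter), n_intra_pairs = nrow(intra),
    n_undefined_skipped = sum(!defined),
    n_species = length(unique(species[dm$labels])),
    theta_prime_definition = theta_prime),
    class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  fmt <- function(m, s) {
    if (is.na(m)) return("NA")
    if (is.null(s)) sprintf("%.4f", m) else sprintf("%.4f +/- %.4f", m, s)
  }
  cat("Divergence summary (", x$n_species, " species; ",
      x$n_inter_pairs, " inter, ", x$n_intra_pairs, " intra pairs, ",
      x$n_undefined_skipped, " undefined skipped)\n", sep = "")
  cat("  All interspecific distance     ",
      fmt(x$mean_interspecific, x$sd_interspecific), "\n")
  cat("  Theta prime                    ", fmt(x$theta_prime, x$sd_theta_prime),
      "\n")
  cat("  Minimum interspecific distance ", fmt(x$min_interspecific, NULL), "\n")
  cat("  All intraspecific distance     ",
      fmt(x$mean_intraspecific, x$sd_intraspecific), "\n")
  cat("  Theta                          ", fmt(x$theta, x$sd_theta), "\n")
  cat("  Coalescent depth               ", fmt(x$coalescent_depth, NULL), "\n")
  invisible(x)
}

#' Write a divergence summary as TSV
#' @param x A `divergence_summary`.
#' @param path Output path.
#' @return Invisibly, `x`.
#' @export
write_divergence_summary <- function(x, path) {
  df <- data.frame(
    measurement = c("All interspecific distance", "Theta prime",
                    "Minimum interspecific distance",
                    "All intraspecific distance", "Theta", "Coalescent depth"),
    value = c(x$mean_interspecific, x$theta_prime, x$min_interspecific,
              x$mean_intraspecific, x$theta, x$coalescent_depth),
    sd = c(x$sd_interspecific, x$sd_theta_prime, NA,
           x$sd_intraspecific, x$sd_theta, NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Barcoding-gap distributions
#'
#' Collects the defined intra- and inter-specific distances and bins both into
#' shared histogram bins `[k*w, (k+1)*w)`; a barcode has a clean gap when the
#' two distributions do not overlap.
#'
#' @param dm A `k2p_dist`.
#' @param species Named species map or `alignment_set`.
#' @param bin_width Positive bin width on the distance scale.
#' @return A list of class `gap_distributions`: `intra_values`, `inter_values`,
#'   `histogram` (data.frame `bin_start`, `bin_end`, `intra`, `inter`),
#'   `bin_width`, `overlap` (TRUE when `min(inter) < max(intra)`).
#' @export
gap_distributions <- function(dm, species, bin_width = 0.005) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("parameter error: bin_width must be > 0")
  }
  if (inherits(species, "alignment_set")) species <- species_map(species)
  pt <- pairwise_table(dm, species)
  defined <- !is.na(pt$d)
  intra <- pt$d[defined & pt$intra]
  inter <- pt$d[defined & !pt$intra]
  vals <- c(intra, inter)
  if (length(vals)) {
    kmax <- max(floor(vals / bin_width))
    bins <- 0:kmax
    hist_of <- function(v) {
      tabulate(floor(v / bin_width) + 1, nbins = kmax + 1)
    }
    histogram <- data.frame(bin_start = bins * bin_width,
                            bin_end = (bins + 1) * bin_width,
                            intra = hist_of(intra), inter = hist_of(inter))
  } else {
    histogram <- data.frame(bin_start = numeric(0), bin_end = numeric(0),
                            intra = integer(0), inter = integer(0))
  }
  overlap <- length(intra) > 0 && length(inter) > 0 &&
    min(inter) < max(intra)
  structure(list(intra_values = intra, inter_values = inter,
                 histogram = histogram, bin_width = bin_width,
                 overlap = overlap),
            class = "gap_distributions")
}

#' @export
print.gap_distributions <- function(x, ...) {
  cat("Barcoding-gap distributions:", length(x$intra_values), "intra,",
      length(x$inter_values), "inter distances; overlap:",
      x$overlap, "\n")
  invisible(x)
}

#' Plot the two barcoding-gap distributions
#'
#' @param x A `gap_distributions` object.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.gap_distributions <- function(x, ...) {
  h <- x$histogram
  rel <- rbind(intra = h$intra / max(1, sum(h$intra)),
               inter = h$inter / max(1, sum(h$inter)))
  graphics::barplot(rel, beside = TRUE,
                    names.arg = formatC(h$bin_start, format = "g"),
                    legend.text = c("intraspecific", "interspecific"),
                    xlab = "K2P distance", ylab = "relative frequency", ...)
  invisible(x)
}

# Exact null distribution of the rank-sum of the first group, tie-aware.
# Ranks are doubled so that midranks become integers; returns a named vector
# of probabilities over achievable (doubled) rank sums.
rank_sum_null <- function(ranks2, n_a) {
  n <- length(ranks2)
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(n_a)])
  # f[[k]] = counts over sums for subsets of size k (index sum+1)
  f <- vector("list", n_a + 1)
  f[[1]] <- c(1, numeric(smax))
  for (k in seq_len(n_a)) f[[k + 1]] <- numeric(smax + 1)
  for (r in ranks2) {
    for (k in rev(seq_len(n_a))) {
      shifted <- c(numeric(r), f[[k]][seq_len(smax + 1 - r)])
      f[[k + 1]] <- f[[k + 1]] + shifted
    }
  }
  counts <- f[[n_a + 1]]
  counts / sum(counts)
}

#' Wilcoxon two-sample (rank-sum) test
#'
#' Two-sided rank-sum test with midranks for ties. The p-value is exact —
#' computed from the full permutation null distribution of the rank sum of
#' the first sample — whenever `choose(n_a + n_b, n_a) <= exact_limit`;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. The two-sided exact p is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b Non-empty numeric vectors. In the barcoding-gap application `a`
#'   holds the intraspecific and `b` the interspecific distances.
#' @param exact_limit Enumeration bound on `choose(n_a + n_b, n_a)`.
#' @return A `rank_test` object: `statistic` (W, the rank sum of `a`),
#'   `p_value`, `method` (`"exact"` or `"normal_approximation"`), `n_a`, `n_b`.
#' @examples
#' wilcoxon_two_sample(c(1, 2), c(3, 4))
#' @export
wilcoxon_two_sample <- function(a, b, exact_limit = 1e6) {
  if (length(a) == 0 || length(b) == 0) {
    stop("parameter error: both samples must be non-empty")
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  if (choose(n, n_a) <= exact_limit) {
    probs <- rank_sum_null(round(2 * r), n_a)
    sums <- seq_along(probs) - 1
    w2 <- round(2 * w)
    p_le <- sum(probs[sums <= w2])
    p_ge <- sum(probs[sums >= w2])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n_a * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  structure(list(statistic = w, p_value = p, method = method,
                 n_a = n_a, n_b = n_b, test = "wilcoxon_two_sample"),
            class = "rank_test")
}

#' Median test
#'
#' Classifies every observation as above versus not-above the pooled median
#' (values equal to the pooled median count as not-above) and tests the
#' resulting 2x2 group-by-side table: Fisher's exact test when any expected
#' cell count is below 5, otherwise a chi-square test with 1 df (no
#' continuity correction).
#'
#' @param a,b Non-empty numeric vectors.
#' @return A `rank_test` object with `statistic` (chi-square statistic, `NA`
#'   on the Fisher path), `p_value`, `method` (`"fisher_exact"` or
#'   `"chi_square"`), `pooled_median`, `table`.
#' @export
median_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("parameter error: both samples must be non-empty")
  }
  m <- stats::median(c(a, b))
  tab <- rbind(a = c(above = sum(a > m), not_above = sum(a <= m)),
               b = c(above = sum(b > m), not_above = sum(b <= m)))
  if (any(colSums(tab) == 0)) {
    # all observations on one side (e.g. all values equal): no evidence
    res <- list(statistic = 0, p_value = 1, method = "degenerate")
  } else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      res <- list(statistic = NA_real_, p_value = p, method = "fisher_exact")
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                  method = "chi_square")
    }
  }
  structure(list(statistic = res$statistic, p_value = res$p_value,
                 method = res$method, n_a = length(a), n_b = length(b),
                 pooled_median = m, table = tab, test = "median_test"),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$test, ": n_a = ", x$n_a, ", n_b = ", x$n_b, sep = "")
  if (!is.null(x$pooled_median)) {
    cat(", pooled median = ", format(x$pooled_median), sep = "")
  }
  cat("\n  statistic = ", format(x$statistic),
      ", p = ", format(x$p_value), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Run both barcoding-gap tests on a distance matrix
#'
#' Convenience wrapper: extracts the defined intraspecific and interspecific
#' distances and applies [wilcoxon_two_sample()] and [median_test()] with the
#' intraspecific sample first.
#'
#' @param dm A `k2p_dist`.
#' @param species Named species map or `alignment_set`.
#' @return List with elements `wilcoxon` and `median`.
#' @export
barcoding_gap_tests <- function(dm, species) {
  gd <- gap_distributions(dm, species)
  list(wilcoxon = wilcoxon_two_sample(gd$intra_values, gd$inter_values),
       median = median_test(gd$intra_values, gd$inter_values))
}
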