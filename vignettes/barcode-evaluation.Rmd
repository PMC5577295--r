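---
title: "Evaluating a short DNA barcode within a genus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a short DNA barcode within a genus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A DNA barcode is useful for a genus when the genetic distance between
species comfortably exceeds the variation within them, and when a query
sequence's closest database match is reliably a conspecific. In recently
radiated plant genera — the motivating case is the alpine medicinal genus
*Rhodiola*, whose roots are widely traded and widely adulterated — neither
is guaranteed: species diverged recently, several species can share an
identical ITS2 haplotype, and the intra- and inter-specific distance
distributions overlap. `barcodegap` implements the standard evaluation
battery for this situation on an aligned barcode matrix with species
labels, plus a synthetic-genus simulator so that the whole battery can be
exercised against known truth.

```{r}
library(barcodegap)
g <- simulate_genus(genus_sim_config(n_species = 8, seed = 1))
aln <- g$alignment
aln
```

# Distances

All distance-based stages use the Kimura 2-parameter (K2P) model. For a
sequence pair, sites where either sequence carries a gap or an IUPAC
ambiguity code are excluded (pairwise deletion); with $P$ the proportion of
transitions (A–G, C–T) and $Q$ the proportion of transversions among the
remaining sites,

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q). $$

When $1-2P-Q \le 0$ or $1-2Q \le 0$ (saturation) or no comparable sites
remain, the entry is *undefined* and is carried as `NA`: downstream
summaries skip undefined pairs and report how many were skipped, rather
than imputing or saturating them, because silent imputation would bias the
divergence parameters. Tree construction refuses matrices with undefined
entries outright, naming the offending pair.

```{r}
dm <- k2p_matrix(aln)
dm
```

# Divergence parameters and the barcoding gap

`divergence_summary()` reports the six standard parameters: mean
interspecific distance, theta prime, and minimum interspecific distance on
the between-species side; mean intraspecific distance, theta, and
coalescent depth (the maximum within-species distance) on the
within-species side.

Two of these have genuinely ambiguous definitions in the literature, and
the package fixes a convention while exposing the alternative:

* **Theta prime** is computed as the unweighted mean over species pairs of
  the mean between-species distance (so heavily sampled species do not
  dominate); `theta_prime = "all_pairs"` gives the literal pooled mean over
  all between-species pairs instead. On survey-style data the two agree to
  the printed precision, which is why published tables rarely say which was
  used.
* **Mean intraspecific distance** pools all within-species pairs; **theta**
  is the unweighted mean over species (with at least two samples) of the
  species' mean — the per-species-weighted alternative. Both are reported,
  so the pooled-versus-weighted question never has to be guessed.

Species with a single sample contribute no intraspecific pairs; when every
species is a singleton the intraspecific parameters are reported as `NA`,
not zero.

```{r}
divergence_summary(dm, aln)
```

`gap_distributions()` bins both distance sets into shared half-open bins
$[k w, (k+1) w)$ (default width $w = 0.005$ substitutions/site, fine enough
to resolve an ITS2-scale gap) and flags overlap when the smallest
between-species distance lies below the largest within-species distance.

Two tests compare the distributions:

* `wilcoxon_two_sample()` — rank sum of the intraspecific sample with
  midranks for ties. The p-value is exact (full enumeration of the
  tie-aware permutation distribution, computed by dynamic programming over
  doubled ranks) whenever $\binom{n_a+n_b}{n_a} \le 10^6$, and a normal
  approximation with tie and continuity corrections otherwise; the
  two-sided p is $\min(1,\, 2\min(P(W \le w), P(W \ge w)))$.
* `median_test()` — observations are classified as above versus not-above
  the pooled median (ties with the median count as not-above, a fixed
  documented convention), and the 2×2 table is tested by Fisher's exact
  test when any expected cell is below 5, else by a chi-square test with
  1 df and no continuity correction.

# Identification

Every sequence is queried against all the others (the query itself is
excluded; its conspecifics — including identical sequences — remain,
because shared haplotypes are exactly the phenomenon under study). Two
rules are provided:

* **best hit**: score each reference by the number of aligned columns
  identical to the query (non-gap); a BLAST-style surrogate that, on a
  fixed alignment of near-identical barcodes, ranks references as a BLAST
  search would, without an external engine;
* **nearest distance**: the references at minimal defined K2P distance.

All co-optimal references contribute their species to the hit set, and the
outcome is CORRECT (hit set is exactly the true species), AMBIGUOUS (true
species among several), or INCORRECT. `tabulate_species()` reduces query
outcomes to one label per species with precedence
INCORRECT > AMBIGUOUS > CORRECT — a species is only "correct" if every one
of its queries is — and reports percentages over species, not queries.

A subtlety worth knowing: the identity score is a monotone transform of the
p-distance, not of the K2P distance, so the two rules can disagree on ties
of equal Hamming distance but different transition/transversion make-up.
On simulated genera they agree for well over 90% of queries; the exact
equivalence (tested in the suite) is between best-hit and
nearest-neighbour-by-p-distance.

# Trees and monophyly

`nj_tree()` implements Saitou–Nei neighbor joining with the
Studier–Keppler criterion; `upgma_tree()` implements average-linkage
agglomeration with node height equal to half the merge distance. Both
break ties deterministically (lowest pair in cluster order) so results are
platform independent; NJ's occasional negative branch lengths are clamped
to zero with the total adjustment recorded as an attribute. Trees are
`ape` `phylo` objects, and `bootstrap_support()` resamples alignment
columns, rebuilds the tree per replicate, and annotates each internal edge
with the percentage of replicates containing the same bipartition
(replicates whose resampled matrix has undefined entries are skipped and
counted).

`monophyly_report()` declares a species discriminated when its tips form a
clade (rooted trees) or one side of an edge bipartition (unrooted trees).
Singleton species cannot fail this test; they are counted as successes by
default, with an `exclude` option, since published discrimination rates
rarely state their convention.

# Diagnostic sites and signatures

A "stable" diagnostic site for a target species is a column where all
target members share one unambiguous base that no other sequence carries.
Two conservative rules matter: any gap or ambiguity code *within the
target* disqualifies the column (fixation must be observed, not assumed),
and a gap or ambiguity in a *non-target* sequence is treated as possibly
matching, rejecting the column — a signature must not misfire on
incomplete data. `find_minimal_combinations()` extends this to joint
signatures: an exhaustive search over target-fixed columns (default up to
3 positions, the size of published ITS2 signatures) for minimal column
sets whose joint state vector can occur in no non-target sequence.
Columns that exclude no non-target sequence are pruned before the search —
they can never appear in a minimal signature, and most alignment columns
are genus-invariant — and a combinatorial guard refuses searches whose
subset count exceeds a configurable ceiling rather than running for hours.
Positions are reported 1-based relative to the analysed alignment; they
are not portable across alignments, so reports accept a column-label map
when a sub-region of a larger alignment is analysed.

```{r}
t5 <- table5_toy()
find_diagnostic_sites(t5, "R_crenulata", column_labels = c(141, 152, 159))
```

# The synthetic genus generator

`simulate_genus()` emulates the data structure the analyses assume — it is
the package's test bed, not a population-genetic simulator. Sequences
evolve by the exact K80 site-substitution process (transition rate
$\alpha$, transversion rates $\beta$ each, $\kappa = \alpha/\beta$,
normalised so a branch of length $d$ accumulates $d$ expected
substitutions per site), so every expectation used in tests has a closed
form: two tips from different species are separated by
$2(\text{depth} + \theta/2)$ expected substitutions per site.

The defaults are fixed to the conditions of an ITS2 survey of a radiated
genus and are not tuning knobs:

| parameter | default | why |
|---|---|---|
| `n_species` | 47 | survey-scale genus |
| `samples_per_species` | 3–6 | a few individuals per species |
| `sequence_length` | 235 | aligned ITS2 length |
| `intraspecific_theta` | 0.008 | within-species divergence scale |
| `interspecific_depth` | 0.010 | so that $2d + \theta = 0.028$, the expected mean interspecific distance |
| `kappa` | 2 | typical nuclear ITS transition bias |
| `n_haplotypes_per_species` | 3 | few-haplotype structure |
| `dominant_weight` | 0.5 | one frequent haplotype per species |
| `haplotype_sharing_prob` | 0.1 | occasional identical haplotypes across sister species |

Species sit on a star phylogeny by default (a radiation), with an optional
varied-depth mode. Sister species are consecutive pairs; with the
configured probability the second of a pair replaces its dominant
haplotype with a verbatim copy of the first's, which is what drives the
minimum interspecific distance to zero and makes the distance
distributions overlap. The first sample of every species is pinned to the
dominant haplotype so that a sharing event is always expressed in the
emitted alignment. The full-size fixture (`make_fixture_suite()`'s
`genus47`) fixes three sharing pairs deterministically
(`haplotype_sharing_prob = 1, n_sharing_pairs = 3`), making the
zero-minimum property a certainty of the study conditions rather than a
coin flip.

Because samples copy their haplotype verbatim, the realised mean
intraspecific distance is $\theta$ times the probability that two samples
of a species carry different haplotypes (about 0.6 under the default
weights), i.e. around 0.005–0.006 against a configured $\theta$ of 0.008;
the tests use a ±0.004 Monte-Carlo band around 0.008 accordingly.

What the generator does **not** emulate: indels and length variation
(columns are positionally homologous by construction; an optional
`gap_rate` exists solely to exercise pairwise deletion), rate variation
across sites, coalescent sampling within species, and introgression beyond
verbatim haplotype copying. Passing tests on synthetic genera therefore
validate the statistics and algorithms, not the biological realism of any
particular survey.

# Problem sizes and determinism

The test suite and the acceptance script run the full battery at the sizes
the methods are designed for: 47-species genera (about 200 sequences, some
20,000 pairwise distances) for divergence, identification and monophyly;
20 simulation replicates for parameter-recovery checks; hundreds of random
oracle comparisons (naive K2P counting, exhaustive rank-sum and
hypergeometric enumeration, additive- and ultrametric-matrix tree
recovery, exhaustive bipartition monophyly) at small sizes where the
oracles are exact. All randomness flows from explicit seeds: the simulator
restores the caller's RNG state, `bootstrap_support()` takes its own seed,
and `run_pipeline()` derives per-stage streams from one master seed so a
single integer reproduces an entire run.

# Known limitations

* The best-hit rule is a surrogate on a fixed global alignment; it does
  not reproduce BLAST E-values or local alignment effects on partial
  queries (mini-barcodes).
* K2P undefined entries are common for toy-sized inputs (three columns
  saturate easily); the pipeline's tree stage can be skipped
  (`tree_methods = NULL`) for such inputs.
* Diagnostic positions refer to the analysed alignment's columns; they are
  only as portable as the alignment itself.
* The median test's treatment of values equal to the pooled median
  (not-above) is a convention; with heavily tied distance data the 2×2
  table can shift under the alternative convention.
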