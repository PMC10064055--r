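---
title: "Models and methods behind phyllonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyllonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllonet)
```

phyllonet implements the statistical pathway of a paired
epiphyte/endophyte phyllosphere survey: OTU preprocessing, community
dissimilarity tests, phylogenetic-signal statistics on the host tree,
weighted bipartite network metrics standardized against
marginal-preserving null models, and coextinction robustness. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Preprocessing model

An `otu_table` is an integer matrix of reads, samples × OTUs. Two rules
mirror standard amplicon practice:

* **Low-count filter.** `filter_low_count()` zeroes any *cell* with fewer
  than `min_reads` (default 10) reads and then drops OTUs that became
  all-zero. We deliberately read the "< 10 reads per sample" rule
  cell-wise: the alternative — dropping an OTU globally whenever any one
  sample has few reads — would delete ubiquitous taxa that happen to be
  rare in a single sample, which is not what the error-correction
  rationale (sporadic PCR/sequencing artefacts) implies.
* **Rarefaction.** `rarefy()` subsamples each sample's reads uniformly
  without replacement (multivariate hypergeometric, via `vegan::rrarefy`)
  to a common depth, by default the minimum sample total. Column sums per
  sample equal the depth exactly. The default stage order is filter →
  rarefy; the filter is an error-correction step and should see raw
  counts, but both stages are exposed separately so the other order is a
  one-line change.

`partition_otus()` is set algebra on the OTU ids present (nonzero in at
least one sample) in each compartment; percentages are reported to two
decimals of the pooled total.

## Community statistics

Distances are Bray–Curtis on Hellinger-transformed counts
(`sqrt(count / sample total)`), the standard combination that keeps
Bray–Curtis in [0, 1] while damping dominant OTUs. NMDS wraps
`vegan::metaMDS` (Kruskal stress-1, isotonic regression with Kruskal's
primary tie treatment, random starts plus a metric-scaling start; we
report the lowest-stress solution and a convergence flag rather than
raising on non-convergence). ANOSIM uses mid-ranked dissimilarities and
the permutation p-value `(1 + #{R_perm >= R_obs}) / (n_perm + 1)`; its
default `n_perm = 9999` is chosen so that p-values of order 1e-4 are
resolvable. The Mantel test is written in-package because the pipeline
needs the *lower* tail: it correlates Bray–Curtis **similarity**
(1 − dissimilarity) with host phylogenetic distance and asks whether the
correlation is smaller than chance (`tail = "less"`), the direction that
corresponds to communities diverging with host phylogenetic distance.
Mantel's default `n_perm = 999` resolves the 0.05 level comfortably.

The richness contrast is a paired t-test on log richness, one-tailed by
default (epiphytes richer than endophytes); with t = 1.92 on 10 degrees
of freedom the upper-tail probability is ≈ 0.042, which is how a
one-tailed reading is distinguished from the two-sided one (≈ 0.084).

## Phylogenetic signal

Both statistics assume a Brownian-motion kernel: `bm_covariance()` returns
the shared root-to-MRCA branch lengths, with Pagel's λ multiplying only
the off-diagonal entries. Blomberg's K is the ratio of observed to
phylogenetically corrected trait variance, scaled by its Brownian
expectation on the same tree, using the GLS (phylogenetic) mean; its
p-value shuffles trait values across tips with an add-one correction
(default 999 permutations), so p can never be exactly 0. Pagel's λ is
profiled maximum likelihood: mean and rate have closed-form profiles, and
λ is optimized on [0, 1] by bounded scalar search with both endpoints
evaluated explicitly (a boundary optimum at λ = 0 or 1 would otherwise be
missed by golden-section search). λ is capped at 1 because larger values
can break positive-semidefiniteness on ultrametric trees. The test is a
likelihood-ratio χ²(1) against λ = 0; when the ratio is numerically zero
— the common outcome for signal-free traits, where λ̂ sits at the 0
boundary — the p-value is exactly 1.

## Network metrics

All four network-level metrics treat read counts as interaction weights
and are invariant to weight rescaling and row/column permutation (tested
properties).

* **H2′** needs the extreme entropies compatible with the observed
  marginals. The maximum is the independence table `r_i c_j / W` in its
  continuous relaxation. The minimum of a concave function over the
  transportation polytope is attained at a vertex; every vertex is
  reachable by repeatedly allocating the full `min(row remainder, column
  remainder)` to some cell. For small webs (≤ 9 rows + columns) we search
  those allocation sequences exhaustively with branch-and-bound, so H2min
  is exact; larger webs use the greedy largest-transfer-first packing,
  whose small deficit vanishes after normalisation at realistic network
  sizes. Entropy bases cancel in H2′; we use natural logs internally and
  base 2 for the connectance entropies, where `2^H` is an effective
  partner count.
* **WNODF** uses strictly decreasing marginal totals as its
  "decreasing fill" condition; tied totals contribute zero. This is the
  marginal-total reading of the weighted overlap/decreasing-fill metric.
  Note that implementations differ in whether rows are ranked by weighted
  totals or by binary fill; phyllonet ranks by weighted totals, so values
  agree with fill-ranking implementations only when the two orderings
  coincide (they do for perfectly nested webs and for webs without fill
  ties).
* **Modularity** maximises Barber's bipartite Q by label propagation
  (each node repeatedly joins the module with the largest gain, ties to
  the lowest module index, a fresh module when every gain is negative)
  with agglomerative merge refinement, best of `n_restarts` runs. On
  webs with up to six species the optimizer provably matches exhaustive
  partition search in the test suite; the restart count is the dial to
  turn up for large difficult webs.

## Null models and z-scores

`swap_web_null()` generates quantitative nulls with the observed row
totals, column totals *and* fill. It starts from a Patefield draw
(`stats::r2dtable`) of the marginals and applies 2×2 submatrix shifts —
moving `min` of a diagonal pair to the anti-diagonal, which preserves both
marginals — accepting shifts that move the fill toward the target until it
matches. Weights must be integers (read counts); non-integer input is
rejected rather than rounded, since Patefield sampling is exact only on
integers. Two guard rails handle rare pathologies: after 500 consecutive
rejected proposals a fill-neutral shift is accepted to reshuffle, and
after 5000 the chain restarts from a fresh marginal draw (relevant only
for unrealistically dense targets, where few fill-increasing moves exist).

`standardize_metric()` reports `z = (obs − exp) / sd_exp` with `exp` and
`sd_exp` the mean and standard deviation over `n_null` independent nulls
(default 1000, each generated from a seed derived from the ensemble seed
and the null's index), plus a two-sided add-one empirical p. A null
ensemble with zero standard deviation yields `z = NA` with an explicit
degenerate flag, never an infinity. `network_null_report()` evaluates all
four metrics on one shared ensemble so the z-scores of a web are mutually
comparable and the ensemble cost is paid once.

## Robustness

`simulate_extinctions()` removes the primary guild in uniformly random
order; a secondary species goes extinct when **all** of its partners are
gone. The rule is topological — weights play no role in the threshold —
following the classical area-based attack-tolerance framework.
The survivor proportion is averaged across replicates (default 100) on
the grid `x = k / n_primary`, and the *mean* curve is fitted
(fit-to-mean, not mean-of-fits) with the one-parameter model
`y = 1 − x^a` by least squares over `log a`. The fitted robustness is the
closed-form area `R = a / (a + 1)`; the trapezoid area of the mean curve
is reported alongside because published figures do not always say which
area was used. A flat curve (y ≡ 1, possible only for webs where every
secondary species retains a partner until the end) has no finite
exponent and raises an error that carries the empirical area.

## Synthetic data: what it emulates and what it does not

`simulate_tree()` draws a pure-birth (Yule) tree and rescales it to unit
height — the simplest ultrametric null, and unit height makes the λ dial
of the trait model directly interpretable as the off-diagonal covariance
fraction. `simulate_trait_bm()` draws multivariate normal traits with the
λ-scaled Brownian covariance.

`simulate_paired_communities()` gives every OTU a host-affinity trait
evolved on the tree — with the signal dial `signal_lambda` for the
epiphyte pool and `endo_lambda` (default 0) for the endophyte pool,
mirroring the empirical contrast between leaf surfaces and leaf
interiors — and maps affinities through a softmax with temperature
`concentration` to per-host compositions; reads are multinomial at fixed
depth. Defaults (11 hosts, 120 OTUs per compartment, depth 10,000, 14%
shared ids, concentration 6) emulate a pooled-sample-per-host-species
design at desk scale: concentration 6 makes OTUs moderately specialised,
which calibration runs show yields near-complete one-tailed Mantel power
at `signal_lambda = 1` with 11–16 hosts while keeping the λ = 0 type-I
rate at its nominal 5%. The generator does **not** emulate sequence-level
error, chimeras, compositional zeros beyond multinomial sampling,
taxonomy, or overdispersion across biological replicates — so passing
tests certify the statistical machinery, not the upstream bioinformatics.

`simulate_network()` is the structure dial for the network stack:
block-diagonal (modular), staircase with strictly decreasing weights
(nested; WNODF = 100 at zero noise by construction), near-diagonal
(specialized; H2′ = 1 for square webs), or a Patefield draw from uniform
marginals (random). The structured part is scaled by an *integer* factor
toward the requested total weight so that zero-noise patterns keep their
exact orderings; the noise fraction is scattered uniformly.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed. The pipeline derives a
per-stage seed by hashing the stage *name* together with the master seed,
so skipping or adding a stage never changes another stage's results, and
two runs with the same config are byte-identical. The test suite and the
acceptance script run everything at desk scale — hundreds of calibration
replicates, 64-tip trees for signal recovery, 10×30 webs for null-model
invariants, 200–1000 member null ensembles — sizes chosen so the whole
suite completes in minutes while keeping Monte-Carlo error well inside
the asserted tolerances; all of them are plain function arguments, so a
study-scale rerun is a matter of turning the dials up.

## Known limitations

* The modularity optimizer is a heuristic; on large webs the reported Q
  is a lower bound on the optimum (more restarts tighten it), and null
  ensembles for Q inherit that property.
* H2min is exact only for small webs; elsewhere the greedy bound makes
  H2′ very slightly conservative.
* The swap-web null assumes integer weights and cannot represent
  completely full target webs reachable only by partial-weight shifts.
* `paired_t_log()` assumes log-transformed differences are approximately
  normal; with 11 hosts the test has limited power against that
  assumption itself.
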