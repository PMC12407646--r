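---
title: "Methods: integrating time-course miRNA and mRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating time-course miRNA and mRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tempomir)
```

`tempomir` infers candidate miRNA-mRNA regulatory pairs from a paired
time-course design: two count layers (miRNA-seq, mRNA-seq) on a shared grid
of days — a proliferating control day (D-1) followed by a post-induction
series (D0 through D16 by default) — with replicate samples, in two or more
condition subtypes. A miRNA is nominated as a regulator when it is
differentially expressed, its temporal profile anti-correlates with a
differentially expressed mRNA, and the pair is supported by a multi-source
target-annotation table. This vignette documents the statistical model at
each stage, every tunable parameter, what the synthetic-data generator does
and does not emulate, and the numerical design choices.

## Normalization

Size factors come from the median-of-ratios procedure: over the features
with nonzero counts in every sample, each sample's factor is the median
ratio of its counts to the per-feature geometric mean across samples. We
additionally rescale factors to geometric mean 1 so that normalized scales
are comparable across runs and layers; this affects nothing downstream
(all statistics are ratio- or rank-based) but makes factors directly
interpretable as relative library sizes. There is no pseudo-reference
fallback: if no feature is observed in every sample the function stops,
because a median over a handful of sporadically detected features is not a
robust reference.

## Differential expression

Each (subtype, day) group is contrasted against the control-day group of
the same subtype, pairwise rather than through one longitudinal model —
per-day DE sets are what the downstream stages consume, and a pairwise
contrast keeps each day's call independent of the trajectory model.
For feature $i$ with normalized group means $\bar\mu_a, \bar\mu_c$:

$$\mathrm{log_2FC} = \log_2\frac{\bar\mu_a + 0.5}{\bar\mu_c + 0.5}$$

The pseudocount 0.5 bounds fold changes when one group is unobserved.
Counts are modelled as negative binomial with
$\mathrm{Var} = \mu + \alpha\mu^2$. The per-feature dispersion is the
method-of-moments estimate from the pooled within-group variance, floored
at $10^{-8}$. With duplicate samples that estimate has about two degrees
of freedom, and plugging it into a normal-tail test inflates the type-I
error several-fold. We therefore moderate: the per-feature estimate is
floored at the across-feature *median* dispersion of the contrast, so
below-median estimates are raised to the common value while above-median
(genuinely noisy) features keep their own. This borrows strength across
features in the same spirit as the shrinkage used by the established DE
packages while remaining a closed-form moment estimator; the test suite
verifies on 2,000 simulated null features (2 vs 2, $\mu = 100$,
$\alpha = 0.1$) that the empirical type-I error at $p < 0.05$ lands in
[0.03, 0.08], and that planted four-fold changes at $\mu = 200$ are
detected with power above 0.8.

The standard error comes from the delta method on the log2 scale and the
Wald p-value is $2(1 - \Phi(|\mathrm{log_2FC}/\mathrm{SE}|))$. Features
with zero counts in both groups are flagged `all-zero` and not tested;
features with zero variance but nonzero means are tested normally (their
moderated dispersion is the cross-feature median). DE calling uses the raw
p-value — `p < 0.05` and `|log2FC| > 1`, both strict, so boundary values
are excluded — and BH-adjusted values are reported alongside for
inspection. Raw-p calling is deliberate: it matches the convention of
per-day DE screens feeding network construction, where the later
annotation and correlation filters do the error control.

## Temporal profiles and soft clustering

Clustering and correlation both operate on replicate-averaged normalized
counts per day. Profiles are z-standardized per feature (population
standard deviation, so a three-point profile (1, 2, 3) maps exactly to
(-1.2247, 0, 1.2247)); constant profiles carry no shape and are dropped
with a message.

Fuzzy c-means minimizes $\sum_{i,k} u_{ik}^m d_{ik}^2$ by alternating

$$u_{ik} = \Big(\sum_j (d_{ik}/d_{ij})^{2/(m-1)}\Big)^{-1}, \qquad
  c_k = \frac{\sum_i u_{ik}^m x_i}{\sum_i u_{ik}^m}$$

with Euclidean distances on the z-scores. The fuzzifier defaults to the
standard data-driven heuristic in the feature count $N$ and dimension $D$,
$m = 1 + (1418/N + 22.05)D^{-2} + (12.33/N + 0.243)
D^{-0.0406\ln N - 0.1134}$, always above 1. Numerical details: centroids
are seeded kmeans++-style under a user seed; because a single seeding can
land in a local optimum that merges one planted shape and splits another,
the fitter runs `nstart = 5` deterministic seedings and keeps the lowest
final objective. Iteration stops when the largest centroid displacement
drops below `tol = 1e-6`; hitting `max_iter` returns the model flagged
unconverged instead of erroring, so long runs remain inspectable. A
feature exactly on a centroid receives membership 1 for it (the update is
singular there), and rows whose distance weights overflow fall back to
their nearest centroid. The objective is recorded every iteration and is
non-increasing, which the tests assert.

The cluster count defaults to 8 per subtype. Because no validation
criterion is fixed by the analysis design, `scan_cluster_count()` offers a
redundancy scan: reject counts where any two centroids correlate above
0.85. Cluster assignment takes the argmax cluster when the membership
reaches `min_membership = 0.5`; the threshold is exposed because
downstream enrichment depends on it.

## Annotation, pairing, and hubs

Interaction records carry a source, an evidence class
(validated/predicted) and, for predictions, a within-source score
percentile — percentiles rather than raw scores because the scales of
heterogeneous databases are not comparable while "top share of each
database" is. The percentile filter keeps predicted records at or below
the cutoff (default 10) per source and always keeps validated records.
The support filter retains a pair with at least one validated record or
predictions from at least two distinct sources; it is exposed as an
optional second-stage refinement (off by default for the main network,
mirroring its use as a follow-up filter on candidate hubs rather than on
the full network). miRNA identifiers are matched case-insensitively after
trimming; database-version aliasing is out of scope.

Every DE miRNA x DE mRNA combination — the per-subtype union of DE
features across days, so that each subtype yields a single network — is
scored by the Spearman correlation (midranks) of the two nine-day
profiles. The correlation window defaults to all days including the
control; it is configurable (for example excluding D-1 or D0) because the
choice is analytic, not forced by the design. Pairs with $\rho < -0.5$
(strict) form the negative network; unannotated ones are retained but
flagged, so both the "negatively correlated" and the "annotated" network
sizes are reportable. Strong pairs additionally require annotation and
$\rho < -0.7$ (strict). The negative reading of both thresholds is used
throughout — no absolute-value variant — since repression is the
mechanism of interest. Hubs are miRNAs ranked by the number of (miRNA,
mRNA) pairs that are strong in *both* subtypes, ties broken
lexicographically so rankings are deterministic.

## Enrichment

Over-representation uses the hypergeometric upper tail including the
observed overlap, $P(X \ge k)$, with BH adjustment across all tests of a
call and significance at FDR < 0.05 (strict). The default universe is the
set of mRNAs actually tested for DE in the subtype (features passing the
all-zero filter): it is the population from which both clusters and
target sets are drawn. Alternative universes (clustered genes only, all
annotated targets) can be passed explicitly. Per-cluster targeted
fractions — the share of a cluster's genes targeted by at least one DE
miRNA — summarize how much of each temporal program is potentially
miRNA-driven.

## The synthetic-data generator

`simulate_experiment()` emulates the study design the pipeline targets:
two subtypes, nine days (control D-1 plus eight post-induction days),
duplicate samples, NB counts. Planted structure: 8 temporal prototype
shapes (monotone up/down and tilted early/mid/late transients plus their
negations, all pairwise Pearson $\le 0.7$, z-scaled); 20 regulator miRNAs,
each with 30 target mRNAs following the regulator's prototype scaled by
`effect_log2fc = 2` on the log2 scale, while the regulator itself follows
the negated shape — anti-correlation is planted by construction, which is
what makes pairing recovery measurable. Shapes are anchored by
subtracting their control-day value so every feature sits exactly at its
baseline mean on D-1; the transient archetypes carry a small monotone
tilt so planted means are strictly distinct across days (tied means would
make the noiseless Spearman limit ill-defined). One regulator receives 10
bonus targets (`hub_bonus_targets`) so a unique ground-truth hub exists;
with exactly equal target counts "the top regulator" would be decided by
noise. Per-sample library factors are drawn log-uniform in [0.5, 2] so
size-factor estimation is non-trivial; baselines are log-normal around
`baseline_mean = 200` (sdlog 0.6), a mid-depth bulk-RNA-seq regime where
the NB quadratic term dominates at `dispersion = 0.1`.

The annotation generator gives every true pair at least one predicted
record with a percentile in (0, 10] — genuine targets rank near the top
of a database, and without this the top-10% filter would erase planted
recall — plus multi-source support for 80% and a validated record for 30%
of true pairs; decoy records (30% of the table) draw pairs outside the
truth with percentiles uniform in (0, 100].

What the generator does **not** emulate: read-level artifacts (mapping,
multi-mapping, GC bias), sequence-determined targeting (seed matches,
binding-site context), correlated dispersion-mean trends, batch effects,
or partially overlapping regulons between subtypes (both subtypes share
the planted truth). Passing recovery tests therefore demonstrates that
the pipeline's statistics recover the structure they assume, not that
real senescence data meet those assumptions.

## Problem sizes and tolerances in the test suite

The suite validates primitives against independent oracles (exhaustive
hypergeometric enumeration for all universes up to 30, a from-definition
BH step-up, brute-force midrank Pearson, covariance eigendecomposition
for PCA; all at 1e-12 or tighter) and the statistical stages by
simulation at deliberately modest sizes chosen to keep each block well
under a minute while leaving Monte-Carlo error far from the pass
boundaries: 2,000 features for DE calibration and size-factor recovery,
4 prototypes x 50 members at post-standardization noise 0.3 for
clustering recovery (ARI >= 0.9, centroid-prototype r >= 0.95 across 5
seeds), and the full default design (100 miRNAs, 2,000 mRNAs, planted
network of 610 pairs) for end-to-end recall >= 0.8 at false-discovery
proportion <= 0.2, with hub recovery in at least 9 of 10 replicate
simulations.

## Known limitations

The DE test is a calibrated simplification, not a reimplementation of the
full shrinkage machinery of the established packages (no dispersion
trend, no outlier refitting, no independent filtering); with more than a
handful of replicates its moderation gains little. Correlation over nine
time points has limited resolution — the null probability of
$\hat\rho < -0.5$ is a few percent per pair, which is why annotation
intersecting matters. Hub ranking counts pairs; it does not model shared
targets between miRNAs or partial correlation, and positive miRNA-mRNA
relationships are out of scope by design.
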