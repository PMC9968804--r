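---
title: "Methods: 3D-genome-guided miRNA panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D-genome-guided miRNA panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Serum miRNA expression panels can discriminate disease cases from controls,
but panels selected purely by per-miRNA association statistics tend to be
large and redundant. The hypothesis behind this package is that the 3D
organization of the genome carries selection-relevant structure: miRNA genes
that are close in the nucleus (for example within the same topologically
associating domain) tend to be co-regulated, so a panel that takes a few
*representatives per spatial cluster* can be smaller than an association-only
panel while retaining its discriminative power.

`mir3d` implements and evaluates that idea end to end:

1. reconstruct a 3D genome model from a Hi-C-like contact matrix,
2. place each miRNA's transcription start site (TSS) in the model,
3. cluster the placed miRNAs by spatial density (DBSCAN),
4. build a compact panel with per-cluster proportional representation,
5. score panels by leave-one-out cross-validation (LOOCV) of standard
   classifiers.

Real serum cohorts and high-resolution Hi-C maps are large and access
controlled, so the package ships a calibrated synthetic-data generator with a
known planted signal; every claim the pipeline makes can be checked against
that ground truth.

# Stage 1: structure reconstruction

## Contacts to target distances

Hi-C counts decay with spatial distance. We invert the standard power-law
model: for a pairwise contact count $c_{ij} > 0$ the target (wish) distance is

$$ d_{ij} = c_{ij}^{-\alpha}, \qquad \alpha > 0, $$

with `alpha = 1` by default. Bin pairs with zero observed contacts carry no
distance information; they are capped at `cap_factor` (default 1.5) times the
largest finite target distance, which repels them without letting an absent
observation dominate the objective (`contacts_to_distances()`).

## Multi-restart stress minimization

The embedding minimizes normalized Kruskal stress

$$ \sigma(X) = \sqrt{\frac{\sum_{i<j} (\hat d_{ij}(X) - d_{ij})^2}
                          {\sum_{i<j} d_{ij}^2}}, $$

where $\hat d_{ij}(X)$ are the realized Euclidean distances of the candidate
coordinates $X \in \mathbb{R}^{n \times 3}$. Each restart starts from random
coordinates (seeded from its own substream, see "Reproducibility") and runs
SMACOF majorization (the Guttman transform), which decreases stress
monotonically; a BFGS polish with the analytic gradient of the raw stress is
then applied and kept only when it improves the result. `embed_structure()`
runs `n_restarts` such fits (default 300, matching common practice for
conformation ensembles) and returns the best-matched conformation, i.e. the
restart with minimal stress. The per-restart final stresses are retained so
the selection is auditable.

Because restart $r$ always draws from the substream keyed by $r$, the restart
sets of two runs with the same seed are nested: increasing `n_restarts` can
never increase the selected stress.

## Comparing structures

Reconstructions are compared by Procrustes RMSD (`procrustes_rmsd()`):
both point sets are centered, the optimal rotation is obtained from the SVD of
the cross-covariance (Kabsch–Umeyama), a single uniform scale is fitted, and
the root-mean-square residual is reported. Reflection is allowed by default
because a distance-only objective cannot determine chirality.

## Placing miRNAs

`map_tss_to_coords()` assigns each *uniquely* annotated miRNA to the genomic
bin containing its TSS under 0-based half-open bin intervals (a TSS exactly on
a bin boundary belongs to the following bin). miRNAs with multiple annotation
records (multimapped) or TSSs outside the modeled bins are dropped, with
logged counts; ambiguity is treated as a data-quality problem, not resolved by
guessing.

# Stage 2: expression profiling

Raw expression is standardized per sample by the mean of three designated
internal-control miRNAs (`normalize_by_controls()`). This removes per-sample
technical scale exactly: multiplying a sample's raw column by any $c > 0$
leaves its normalized values unchanged (up to one floating-point rounding for
non-power-of-two $c$).

Two record filters follow, both idempotent and order-commutative:

- `filter_low_expression()` keeps a miRNA whose signal reaches `min_score`
  (default 5) in at least `min_samples` samples (default 76% of the cohort);
- `filter_ambiguous()` keeps only miRNAs with a single uniquely mapped
  annotation record.

# Stage 3: spatial selection

## Association scores

`spearman_scores()` computes each miRNA's Spearman rank correlation (mid-rank
ties) against the 0/1 case label with a two-sided p-value from the
t approximation. Rank correlation against a binary label is a monotone
transform of the rank-sum statistic, making the scores robust to the heavy
right tail of expression data.

## DBSCAN with singleton promotion

`dbscan_cluster()` is a deterministic DBSCAN: a point is *core* when its
closed eps-neighborhood (itself included) holds at least `min_pts` points;
clusters are connected components of core points; border points join the
nearest core point's cluster (ties: smaller distance, then smaller miRNA id);
and every noise point is *promoted to its own singleton cluster* so that the
subsequent apportionment sees a complete partition. Cluster ids are assigned
by each cluster's smallest member id, making the labeling invariant to input
row order.

The function default `eps = 3` reflects the published protocol's value in the
units of its (undeposited) source model. The pipeline default for the
synthetic data is `eps = 0.25`, because the $d = 1/c$ conversion puts
single-contact pairs at unit distance, an order of magnitude below that scale.
Neighborhood radii are only meaningful relative to an embedding's arbitrary
length unit; this is a genuine free parameter of the method, not a constant.

## Proportional representatives

`proportional_representatives()` allocates the `m` panel seats (default 20)
across clusters proportionally to cluster size using largest-remainder
apportionment: each cluster receives the floor of its exact quota
$m \cdot n_c / N$, and leftover seats go to the largest fractional remainders
(ties: larger cluster, then lexicographic id). Within a cluster, seats are
filled by descending $|\rho|$. The selected total is exactly
$\min(m, N)$ and each allocation respects its cluster size.

Largest remainder minimizes the total absolute deviation from the exact
quotas among integer allocations, which is why it was chosen. One classical
caveat: it is *not* seat-monotone (the Alabama paradox) — increasing `m` by
one can reduce some cluster's allocation. The tests assert conservation,
size caps, and quota-deviation optimality, which are the properties that
actually hold.

Three reference panels are built alongside: `all` (every filtered miRNA),
`top_scc` (top-k by $|\rho|$ with $p <$ `p_max`), and a size-matched `random`
baseline.

# Stage 4: LOOCV evaluation

`loocv_predict()` holds out one sample at a time, fits on the rest, and
scores the held-out sample. Four model families are supported: RBF-kernel
support vector classification (margins mapped through a logistic so margin 0
is score 0.5), linear and RBF support vector regression, and k-nearest
neighbor regression. SVM features are z-scored using the *training fold's*
means and SDs; `gamma = "scale"` is likewise resolved per fold. Calls use the
0.5 score cutoff.

Two selection modes are provided, and the distinction matters:

- `fixed_panel` evaluates a panel selected once on the full data set — the
  protocol of the published analyses this package models. Because selection
  has seen every label, LOOCV estimates are optimistically biased. The risk
  is logged at run time and flagged on the result
  (`attr(pred, "selection_leakage")`).
- `nested` re-derives the panel inside every training fold via a
  user-supplied `panel_builder`, so selection never sees the held-out label.
  The per-fold panels are returned for audit. Perturbing a held-out sample's
  label provably cannot change that fold's panel, and the tests assert it.

`compute_metrics()` reports accuracy, precision, recall, F1 (from the calls),
AUC (Mann–Whitney rank statistic, ties counted half) and AUPR (step-wise
average precision) from the continuous scores. `curves()` emits ROC/PR points
whose trapezoidal ROC area equals the Mann–Whitney AUC exactly.

# The synthetic-data generator

`simulate_dataset()` produces a complete input set with known ground truth.
What it emulates:

- a toy annotation genome (24 chromosomes x 22 bins of 100 kb) with a 3D
  model covering two chromosomes, each built as a compacted informative
  domain plus filler bins (`simulate_structure()`: seeded random walk with
  within-domain compaction 0.85 and a chromosome-territory reflecting
  boundary);
- Poisson-noised contacts from the true structure under the same power law
  the reconstruction inverts ($k\,d^{-\beta}$, `structure_to_contacts()`);
- 300 miRNAs: 20 informative ones planted in the informative domains, the
  rest placed uniformly outside them; ~10% get duplicate annotation records
  (literal multimapping) and 5% are low-expression background;
- log-normal expression with a case-group shift of `effect_size` (default
  1.0) times the log-SD for informative miRNAs only, three stable
  internal-control miRNAs, and a per-sample technical scale factor
  (`exp(N(0, 0.3))`) that the control normalization must remove.

What it deliberately does not emulate: read-count mechanics (no library-size
or count-noise model beyond the scale factor), genomic sequence, chromatin
compartments beyond two-level domains, correlated miRNA co-expression within
background, or batch structure. It is a validation instrument, not a cohort
simulator: strong enough that the pipeline must work to succeed, simple
enough that every stage's expected behavior is computable.

# Reproducibility

A single master seed drives everything. Each stage and each embedding restart
derives its own substream with `substream_seed(seed, offset)`, so stages can
be rerun individually (`run_pipeline(stages = ...)`) and still match a full
run byte for byte; `manifest.json` records the config, package version and
md5 checksums of every artifact. All on-disk numeric formats are serialized
at full precision (`%.17g`) so write/read round trips are bit-identical.

# Typical problem sizes

The defaults run a 44-bin embedding with 300 restarts, ~260 post-filter
miRNAs over 200 samples, and a 4-panel x 4-family LOOCV grid in roughly two
minutes on one CPU. The embedding is the only stage whose cost is sensitive
to size (SMACOF is $O(n^2)$ per iteration); hundreds of bins remain
comfortable, thousands call for fewer restarts.

# A worked run

```{r, eval = FALSE}
library(mir3d)
cfg <- default_config(seed = 1)
man <- run_pipeline(cfg, outdir = "run1")
read.csv(file.path(man$outdir, "metrics.csv"))
```

See the README for the printed numbers of this exact run.

# Limitations

- The contact power law and its inversion share the same functional form in
  the synthetic study; real Hi-C distance decay is locus-dependent.
- `eps` must be calibrated to the embedding's length unit; there is no
  universal default.
- `fixed_panel` LOOCV reproduces, and therefore inherits, the selection
  leakage of the published protocol; use `nested` mode for unbiased
  estimates.
- Largest-remainder apportionment is not seat-monotone (see above).
- With `d = c^{-\alpha}`, zero-contact pairs are handled by a cap rather
  than a likelihood model; very sparse matrices will embed poorly.
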