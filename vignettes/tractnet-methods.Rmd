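---
title: "Structural connectome analysis with tractnet: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural connectome analysis with tractnet: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractnet)
```

## The analysis in one paragraph

`tractnet` implements a complete structural brain-network pipeline of the
kind used in patient–control white-matter connectivity studies: deterministic
streamline tractography on a diffusion-tensor field, construction of a
90-node weighted connectome under two edge-weighting strategies, weighted and
unweighted graph metrics evaluated along a 40-level network-threshold
schedule, and group statistics on the resulting metric curves — ANCOVAs on
the total area under each curve (AUC), point-by-point permutation tests with
multi-threshold permutation correction (MTPC), and partial Spearman
correlations with clinical measures. Because subject-level imaging data of
this kind is rarely shareable, the package also ships a first-class
synthetic-data module (tensor phantoms, toy parcellations, simulated
cohorts) so that every stage can be exercised and calibrated end to end.

## Tractography

Tracking is deterministic: from every seed the streamline follows the
principal eigenvector of the trilinearly interpolated diffusion tensor with
Euler steps, bidirectionally, the eigenvector sign at each step chosen to
continue the previous direction. Seeds are placed on a dense "super-
resolution" grid (default spacing 0.5 mm, i.e. eight seeds per 1 mm voxel).
A trace terminates when

* fractional anisotropy (FA) at the next point falls below `fa_threshold`
  (default 0.2; the seed itself must also pass),
* the angle between consecutive principal directions exceeds
  `angle_threshold` (default 40°) — the over-limit point is kept, the turn
  is not taken,
* the streamline leaves the mask or the volume, or
* its length reaches `max_length` (default 250 mm, a loop guard).

The tensor field interface is deliberately simple (a voxel array of six
unique tensor components with voxel geometry); interpolation is trilinear on
the components with the eigendecomposition done at the interpolated point.
The field's convention that low-FA points both reject seeds and stop
propagation means an isotropic (FA = 0.1) volume yields no streamlines at
all. Integration order, interpolation scheme and bidirectionality are
documented package choices: deterministic pipelines differ on these details
and any fixed choice is defensible; ours favour smoothness and independence
from seed iteration order.

### Phantoms

Four tensor-field geometries support testing: `straight_bundle` (axially
symmetric tensors of configurable FA along x), `curved_bundle` (a tangential
annulus around the grid centre whose reference radius is chosen so a 1 mm
chord step turns by `curvature_per_step` degrees — convenient for probing
the angle rule), `crossing` (two orthogonal bundles averaged in the overlap,
reproducing the crossing-fibre FA drop), and `isotropic`. Background voxels
get random-orientation tensors at `background_fa`.

## Connectome construction

Streamlines connect region `i` to region `j` when their two *endpoints* lie
in those regions (nearest-voxel label lookup; background endpoints and
same-region pairs contribute nothing). Pass-through regions are ignored —
termination connectivity, not visitation. Two weighting strategies are
provided:

* **length-adjusted**: \(w_{ij} = \tfrac12 \sum_{m=1}^{N_{ij}} 1/l_m\) over
  the \(N_{ij}\) streamlines of the edge with lengths \(l_m\) (mm). Dense
  seeding over-counts long streamlines in proportion to their length; the
  reciprocal sum removes that distal bias. The sum runs over exactly the
  \(N_{ij}\) streamlines.
* **volume-adjusted**: \(w_{ij} = 2N_{ij}/(V_i + V_j)\) with \(V\) the
  end-node volumes (mm³), correcting seed-count bias from node size and,
  with it, head size. Doubling every node volume halves every weight.

Each traced streamline counts once; no geometric deduplication of
near-parallel trajectories from adjacent seeds is attempted (a documented
limitation of dense deterministic seeding).

## Graph metrics

Metrics follow the standard weighted-network conventions, with edge weights
first normalised by the network maximum so \(\hat w_{ij} \in [0,1]\):
degree and strength (row sums of the adjacency and of \(\hat w\)),
clustering, global/nodal efficiency and characteristic path length
(unweighted distances are hop counts, weighted distances sum \(1/\hat w\)
along the route), local efficiency (efficiency of each node's neighbourhood
subgraph) and betweenness centrality (normalised by \((n-1)(n-2)\); a
`strict_print_norm` flag exposes an \((n-1)^2\) variant). For the weighted
clustering and local efficiency we use the cube-root (geometric-mean)
conventions, under which every weighted metric reduces *exactly* to its
unweighted counterpart on binary networks — a property the test suite
asserts at `1e-12`, alongside equality with exhaustive brute-force
implementations (Floyd–Warshall, triangle enumeration, shortest-path
counting) on random graphs of up to 8 nodes.

Distances between disconnected nodes contribute zero to efficiency and are
excluded from path-length averages (an isolated node's path length is
missing, not infinite).

**Small-worldness** is \(S = (C/C_{rand})/(L/L_{rand})\), with the null
values averaged over 100 degree-preserving Maslov–Sneppen rewirings
(10 × |E| swap attempts each, weights travelling with the swapped edges;
implemented in C++ and driven by R's RNG for reproducibility). A complete
graph cannot be rewired, so \(S = 1\) exactly — a useful sanity check.
Whether such nulls should also preserve the weight-to-topology assignment is
genuinely open; carrying weights with edges preserves the weight *multiset*
while randomising placement, which is the common reading of "randomly
re-wired".

## Threshold schedules and metric curves

Low-weight edges are the least reproducible part of tractography networks,
and most graph metrics are confounded by edge count. Both issues are handled
by evaluating every metric across a schedule of 40 thresholds:

* the **density schedule** spans \((0, d_{max}]\) in 40 equal steps, where
  \(d_{max}\) is the largest density at which *all* subjects can be
  density-matched (the sparsest subject's native density). At each level the
  top \(k\) edges by weight are retained (ties broken by fixed lexicographic
  node-pair order), so all subjects have identical edge counts — the tests
  assert this exactly;
* the **weight schedule** gives unweighted degree (itself an edge-density
  index) absolute edge-weight thresholds: the "average subject" is the
  element-wise mean weight matrix, and the threshold at each density level
  is the smallest weight retained when the average subject is thresholded to
  that density. The phrase "average edge weight at each density" admits a
  second reading — the mean of the retained weights — which is available as
  `rule = "mean_retained"`; neither is asserted as the original.

Per-subject metric curves across the 40 levels are summarised by the
trapezoidal AUC over the threshold axis. Degree and strength curves are
computed by a closed-form sorted-cumulative-sum path (identical to
thresholding each network explicitly; the equality is a regression test)
because they sit inside the calibration loops.

## Group statistics

* **AUC ANCOVA** — the group F statistic from `auc ~ covariates + group`.
  Parametric mode screens residual normality (Shapiro) and will move to a
  log10 scale when that rescues Gaussianity; permutation mode keeps the same
  F statistic and derives p from a Freedman–Lane null (permute
  reduced-model residuals, re-add the reduced fit, recompute F; default
  10000 permutations, \(p = (b+1)/(m+1)\), with an exact enumeration option
  for \(n \le 9\)).
* **MTPC** — per-threshold covariate-adjusted group t statistics; the
  permutation null of \(\max_\tau |t|\) yields the two-tailed FWE-adjusted
  critical value (95th percentile) and \(p_{FWE}\) for the peak. Runs of at
  least `cluster_min = 3` consecutive supra-critical thresholds form
  clusters; a cluster's trapezoidal area of \(|t|\) above the critical value
  (AUC\(_{MTPC}\)) must exceed the mean analogous null-cluster area
  (AUC\(_{crit}\)) for significance. We integrate the *excess* above the
  critical value by default (`cluster_area = "total"` integrates \(|t|\)
  itself) — the contract text we follow states the above-critical area, and
  the excess area is the more conservative of the two readings.
* **Partial Spearman correlations** — rank-transform, residualise both
  ranks on covariate ranks, correlate the residuals;
  \(df = n - 2 - k\); pairwise deletion of incomplete rows (ANCOVA uses
  listwise deletion). Bonferroni adjustment is a plain `min(1, m p)`.

Covariate presets mirror the analysis plan this pipeline supports: age and
sex always; total intracranial volume added under the length-adjusted
weighting (the only strategy without its own head-size correction);
pre-morbid IQ added for cognition correlations.

## The synthetic cohort generator

The generator is the package's model of the study conditions, not a tuning
knob. One template network per cohort is drawn as a Watts–Strogatz ring
lattice (neighbourhood chosen to hit `base_density`, default 0.15; rewiring
probability 0.1) — guaranteeing the small-world regime real structural
networks occupy — with lognormal, ring-distance-decaying edge weights
(σ = 0.5, decay scale 15 hops), mimicking the heavy-tailed distance-biased
weights tractography produces. Each subject multiplies the template weights
by i.i.d. lognormal noise (σ = 0.25). Patients additionally (a) lose each
*weak-quartile* template edge with probability `weak_edge_deletion_prob` and
(b) have all weights multiplied by `weight_attenuation` — fewer and weaker
weak edges with the strong backbone intact. Covariates: age uniform on
51–84 years, balanced sex, total intracranial volume normal(1430, 90) × 10³
mm³, pre-morbid IQ normal(106, 12); optional cognitive and patient-only
disease-severity columns with controllable missingness; optional linear
covariate effects on log-weights (off by default).

What the generator does **not** emulate: raw DWI signal or scanner noise
(tensors are generated directly), spatially correlated subject noise,
registration/parcellation error, and the second-order pattern of higher
weighted nodal efficiency in patients sometimes reported alongside edge
loss. Passing calibration on these cohorts therefore demonstrates the
statistical machinery is correct, not that any particular clinical effect
would be detected in real data.

### A structural identity worth knowing

Because every metric is computed on max-normalised weights, a *global*
multiplicative attenuation of a subject's weights leaves strength and all
other normalised-weight metrics at matched density unchanged — the injected
`weight_attenuation` is mathematically invisible there. It is, however,
strongly visible in the unweighted degree curve across *absolute*
edge-weight thresholds (attenuated subjects retain far fewer edges at every
level), which is exactly where multi-threshold analyses of this design
localise such effects. The package's power calibration therefore targets
the weight-thresholded degree curve; the strength curve responds only to
the weak-edge deletions, a much smaller signal.

## Calibration results the test suite recomputes

With 200 replicate null cohorts (25 + 25 subjects, 90 nodes, 1000
permutations), the AUC permutation-ANCOVA type-I error and the MTPC
family-wise error (rate at which the peak |t| exceeds the FWE-adjusted
critical value) are both required to land inside the exact binomial 95%
interval around 0.05; the full cluster-conjunction procedure, which is
conservative by construction, must stay at or below 0.06. With the injected
patient effect (`weight_attenuation = 0.6`, `weak_edge_deletion_prob = 0.5`,
25 + 25 subjects), the weight-thresholded degree curve must be declared
significant by MTPC in at least 90% of 50 replicates. Watts–Strogatz
cohorts (90 nodes, degree 10, rewiring 0.05) must show small-worldness
above 1 for 100 of 100 subject networks against 100 rewired nulls each,
while Erdős–Rényi graphs (their own null) stay within [0.8, 1.2]. These
problem sizes — desk-scale but statistically meaningful — are the package's
chosen defaults for its own validation and match the parameter values the
pipeline uses in production (40 levels, 100 nulls, 3-threshold clusters);
only the permutation count is reduced from 10000 to 1000 in replicated
calibration loops.

## Numerical choices

* Ties at density thresholds: fixed lexicographic node-pair order, so runs
  are bit-reproducible.
* Permutation p-values use the \((b+1)/(m+1)\) convention; statistic ties
  are compared with a relative guard of `1e-8` so float noise cannot flip a
  count.
* Trapezoidal quadrature throughout (curve AUC and MTPC cluster areas);
  missing curve values drop their panels rather than voiding the curve.
* Degenerate cases: empty networks normalise to all-zero weights; nodes
  with degree < 2 have zero clustering and local efficiency; single-level
  MTPC clusters have zero area; a complete graph is its own rewiring null.
* All stochastic stages take explicit integer seeds and record them (the
  pipeline manifest stores seeds, parameter sets and input hashes).

## Limitations

* Deterministic tensor-line tracking only: no probabilistic tractography,
  no crossing-fibre resolution (the crossing phantom *documents* the FA
  ambiguity rather than solving it), no CSF-contamination correction.
* The streamline/parcellation interface assumes a shared world frame and
  integer labels 1..n; atlas registration is out of scope.
* Global weight attenuation is undetectable in max-normalised metrics (see
  above); analyses of strength differences should always be read jointly
  with the degree-vs-weight-threshold analysis.
* The synthetic cohorts share one template per cohort, so between-subject
  topological variability under the null comes only from noise-free weight
  perturbation plus patient edge deletion; real cohorts vary more.
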