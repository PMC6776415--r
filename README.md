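# tractnet

Structural white-matter connectome construction and multi-threshold network
statistics in R.

Patient–control studies of brain white matter ask whether disease disrupts
the network of fibre pathways linking grey-matter regions. `tractnet`
implements that analysis end to end for researchers working with
diffusion-tensor imaging derivatives:

1. **Deterministic tractography** — streamlines follow the principal
   eigenvector of a trilinearly interpolated tensor field from a dense
   0.5 mm seed grid, stopping when FA < 0.2, when the direction turns by
   more than 40° in one step, or at the mask edge.
2. **Connectome construction** — streamlines whose endpoints terminate in
   regions *i* and *j* define edge (*i*, *j*) of a 90×90 weighted network,
   under two weighting strategies:
   the streamline-length-adjusted weight
   *w*<sub>ij</sub> = ½ Σ<sub>m</sub> 1/*l*<sub>m</sub>
   (removes the distal bias of dense seeding) and the end-node-volume-adjusted
   weight *w*<sub>ij</sub> = 2*N*<sub>ij</sub>/(*V*<sub>i</sub> + *V*<sub>j</sub>)
   (removes node-size and head-size bias).
3. **Graph metrics** — degree, strength, clustering, global/local
   efficiency, characteristic path length, betweenness centrality
   (weighted and unweighted, on max-normalised weights), and
   small-worldness *S* = (*C*/*C*<sub>rand</sub>)/(*L*/*L*<sub>rand</sub>)
   against 100 degree-preserving rewired nulls.
4. **Multi-threshold curves** — every metric is evaluated at 40 evenly
   spaced edge-density levels (degree at 40 matched edge-weight levels),
   giving per-subject metric curves summarised by their trapezoidal AUC.
5. **Group statistics** — parametric and Freedman–Lane permutation ANCOVAs
   on the AUCs (10000 permutations by default), point-by-point group tests
   with multi-threshold permutation correction (MTPC: max-|t| FWE critical
   value, ≥3-threshold clusters, cluster area above the critical value must
   beat the null-cluster average), partial Spearman correlations with
   clinical measures, and Bonferroni adjustment.

A first-class synthetic-data module (tensor phantoms, toy parcellations,
simulated two-group cohorts with controllable weak-edge deletion and weight
attenuation) makes the whole pipeline testable without any imaging data.
See the methods vignette (`vignettes/tractnet-methods.Rmd`) for the models,
conventions and design decisions.

## Worked example

Simulate a 15 + 15 cohort in which patients lose 40% of their weak-quartile
edges and have all edge weights attenuated to 0.7, then run the full
curve + statistics pipeline:

```r
library(tractnet)

cfg <- run_config(
  cohort = cohort_spec(n_controls = 15, n_patients = 15,
                       weight_attenuation = 0.7,
                       weak_edge_deletion_prob = 0.4, seed = 42),
  metrics = c("degree", "strength"),
  n_perm = 2000, seed = 42)
res <- run_pipeline(cfg)
print(res)
```

```
<pipeline_result> 30 subjects, metrics: degree, strength
# A tibble: 2 × 10
  metric statistic   df1   df2 p.value mode  transform n_perm     n p.bonferroni
  <chr>      <dbl> <int> <int>   <dbl> <chr> <chr>      <int> <int>        <dbl>
1 degree  5400.        1    26 5.00e-4 perm… none        2000    30     0.001000
2 stren…     0.164     1    26 6.80e-1 perm… none        2000    30     1
# A tibble: 2 × 11
  metric     t_max    tau    df    p_fwe t_crit n_clusters auc_mtpc auc_crit
  <chr>      <dbl>  <dbl> <int>    <dbl>  <dbl>      <int>    <dbl>    <dbl>
1 degree   -64.4   0.437     26 0.000500   2.25          1     61.0   0.613
2 strength   0.470 0.0418    26 0.721      2.22          0     NA     0.0528
```

The injected effect is found where it should be: patients retain far fewer
edges at every absolute edge-weight threshold, so the degree AUC ANCOVA
(F(1,26) ≈ 5400, permutation p = 5×10⁻⁴) and the degree MTPC (peak
t = −64.4 at weight threshold 0.437, p_FWE = 5×10⁻⁴, one supra-critical
cluster whose area 61.0 dwarfs the null-cluster average 0.613) are both
decisive. Strength at matched density is insensitive to a global weight
attenuation (weights are max-normalised per network), so its tests are
correctly null — see the vignette for why.

The average subject's network sits in the small-world regime:

```r
small_worldness(res$schedules$average_subject, n_null = 100, seed = 42)
#> <small_world_result> S = 2.491 (C = 0.389, L = 2.110, C_rand = 0.142, L_rand = 1.919, 100 nulls)
```

`autoplot()` methods draw metric curves (`autoplot(res$curves,
covariates = res$covariates)`) and MTPC traces
(`autoplot(res$mtpc$degree)`); `tidy()`/`glance()` return tibbles from
fitted results. A thin command-line wrapper over the same functions lives
at `inst/cli/tractnet.R` (verbs `simulate`, `phantom`, `track`, `build`,
`metrics`, `run`).

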