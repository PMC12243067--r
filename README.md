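# brainctrl

Functional network controllability analysis for clinical brain cohorts.

## The problem

Cognitive impairment in multiple sclerosis (MS) is linked to functional
changes in subcortical grey matter, most prominently the thalamus. Network
control theory offers a mechanistic reading of such changes: treating a
subject's functional connectome as the coupling matrix of a linear dynamical
system, one can ask how easily each region steers brain-wide activity.
`brainctrl` implements that analysis end to end for cohort studies — from
regional resting-state time series to covariate-adjusted group statistics and
patient classification — together with a fully specified synthetic cohort
generator, so every step is testable against known ground truth.

The package is aimed at methods researchers in functional connectomics who
want a reproducible, oracle-tested reference implementation of regional
controllability metrics and the statistical scaffolding around them.

## The model

For each subject, the functional connectome `C` is the matrix of pairwise
Pearson correlations between regional time series (diagonal stored as 0).
It is stabilized into discrete-time linear dynamics

    x_{t+1} = A x_t + B u_t,      A = C / (1 + sigma_max(C)),

where `sigma_max` is the largest singular value, so that `rho(A) < 1`. Three
regional metrics are computed from `A = V diag(lambda) V'`:

* **Average controllability** — the trace of the infinite-horizon
  controllability Gramian with single-node input `B = e_i`, i.e. the solution
  of the discrete Lyapunov equation `A W A' − W + e_i e_i' = 0`; for
  symmetric `A` this is `AC_i = sum_j v_ij^2 / (1 − lambda_j^2) ≥ 1`. High
  values mark regions that push the brain into nearby, low-energy states.
* **Modal controllability** — `phi_i = sum_j (1 − lambda_j^2) v_ij^2`, a
  region's ability to excite fast-decaying, hard-to-reach modes.
* **Activation energy** — the minimum control energy `E = v' W(T)^{-1} v`
  of a state transition over horizon `T` on the shifted continuous system
  `A_c = A − I`, with `W(T) = ∫_0^T e^{A_c t} B B' e^{A_c' t} dt`. Two
  attribution conventions ship: `single_driver` (default; region `i` is the
  sole driver moving the brain to a uniform target state) and
  `whole_brain_control` (all regions driven, region `i` the unit target).

Region-level metrics are averaged to the whole brain, seven cortical
networks plus the subcortex, and seven subcortical nuclei (including a
16-region thalamus). Group contrasts (HC vs MS, HC vs CPMS, HC vs CIMS,
CPMS vs CIMS) use Freedman–Lane permutation tests of the group regression
t statistic with age and sex as nuisance covariates, Benjamini–Hochberg FDR
within each metric-by-level family. Cognitive phenotyping follows the
impairment rule: a patient scoring at least 1.5 control SDs below the
control mean on at least two subtests is cognitively impaired (CIMS),
otherwise preserved (CPMS). Linear SVMs with repeated stratified
cross-validation classify MS vs HC, CIMS vs CPMS, and disability strata
(EDSS < 4 vs ≥ 4) from thalamic controllability and/or thalamic volume.

## Worked example

Generate a synthetic cohort with the default study structure (27 HC, 47
CPMS, 55 CIMS) at a reduced 100-region scale, compute controllability
profiles, and test the thalamic contrast:

```r
library(brainctrl)

spec    <- cohortSpec(nRegions = 100L, nThalamic = 16L)
cohort  <- generateCohort(spec, seed = 1)
profiles <- computeProfiles(cohort)            # SummarizedExperiment
agg     <- aggregateMetrics(profiles)
pheno   <- cohortPhenotypes(cohort@manifest)

comp <- runGroupComparisons(agg, cohort@manifest, status = pheno$status,
                            nPerm = 2000, seed = 1, levels = "nucleus",
                            contrasts = "HC_vs_MS")
subset(comp, unit == "thalamus")
#>  contrast     unit  metric statistic direction p_perm  p_fdr
#>  HC_vs_MS thalamus average      5.85         1 0.0005 0.0035
#>  HC_vs_MS thalamus   modal     -2.44        -1 0.0185 0.1294
#>  HC_vs_MS thalamus  energy     -4.15        -1 0.0005 0.0035
```

The generator strengthens thalamo-cortical coupling in patients, and the
pipeline recovers the expected signature: thalamic average controllability
is significantly *higher* in MS (positive statistic, FDR-corrected
p = 0.0035 within the seven-nucleus family), while modal controllability
and activation energy move *down*.

```r
cls <- runClassification(agg, cohort@manifest, status = pheno$status,
                         repeats = 20, seed = 1)
subset(cls, metric == "auc" & task != "EDSS_lt4_vs_ge4")
#>          task     feature_set metric  mean     sd
#>      MS_vs_HC controllability    auc 0.851 0.0783
#>      MS_vs_HC          volume    auc 0.674 0.1118
#>      MS_vs_HC     combination    auc 0.863 0.0805
#>  CIMS_vs_CPMS controllability    auc 0.685 0.1156
#>  CIMS_vs_CPMS          volume    auc 0.479 0.1162
#>  CIMS_vs_CPMS     combination    auc 0.685 0.0979
```

Thalamic volume separates MS from HC (AUC 0.67) but is uninformative
between the cognitive subgroups (AUC 0.48, chance), where thalamic
controllability still classifies well above chance (AUC 0.69) — the
dissociation the generator encodes and the analysis is designed to expose.

The whole pipeline can also be run in one call (or from the shell via
`inst/scripts/run-pipeline.R`):

```r
runPipeline(demoConfig(seed = 7), outDir = "demo_run")
```

which writes the cohort, per-subject profiles, aggregated metrics,
phenotypes, the comparison table and the classification table, with
checksummed stage skipping on rerun.

## The methods vignette

`vignettes/network-controllability.Rmd` documents the model and its
conventions, every tunable parameter with its default and rationale, what
the synthetic generator emulates (and deliberately does not), and the
numerical choices and limitations.
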