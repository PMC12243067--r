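---
title: "Network controllability analysis of synthetic clinical cohorts: models, conventions, and design choices"
author: "brainctrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network controllability analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the linear model
behind the controllability metrics, the conventions chosen where several are
in circulation, what the synthetic cohort generator does and does not
emulate, and the numerical decisions a maintainer would want written down.

## From time series to a linear system

Each subject contributes a regions-by-timepoints matrix of resting-state
signals. The functional connectome `C` is the pairwise Pearson correlation
matrix with the diagonal stored as zero; self-connections are excluded
before stabilization because retaining unit self-loops inflates every
Gramian without adding subject information. Negative correlations are kept
as-is by default (`pearsonFC(..., negative = "keep")`); absolute-value and
zero-clipping variants exist so that this choice is auditable rather than
silent. No temporal filtering, scrubbing, or global-signal regression is
performed — the package starts where preprocessing ends.

The connectome is stabilized into discrete-time dynamics
`A = C / (1 + sigma_max(C))`, which guarantees a spectral radius strictly
below one. The largest singular value rather than the largest absolute
eigenvalue is used so that the same rule extends to non-symmetric couplings,
although all matrices produced in this package are symmetric.

## The three metrics and their conventions

**Average controllability** is the trace of the infinite-horizon discrete
controllability Gramian with a single-node input, i.e. the solution trace of
the Lyapunov equation `A W A' − W + e_i e_i' = 0`. For symmetric `A` with
orthonormal eigendecomposition this equals
`sum_j v_ij^2 / (1 − lambda_j^2)`, which *is* the exact Lyapunov solution,
not an approximation; the test suite verifies it against a truncated-series
oracle at 1e-8 relative on dozens of random systems. Every value is at
least 1 (the k = 0 term of the series).

**Modal controllability** is `phi_i = sum_j (1 − lambda_j^2) v_ij^2`.
Because the eigenbasis is orthonormal, `phi_i = 1 − (A^2)_ii` exactly; the
tests exploit this eigen-free identity as an independent oracle, along with
the trace identity `sum_i phi_i = N − sum_j lambda_j^2`. Complex spectra
are rejected rather than silently truncated: the formula is only defined for
real symmetric systems.

**Activation energy** is the minimum control energy of a state transition
over horizon `T = 1` on the shifted continuous-time system `A_c = A − I`,
whose eigenvalues are all negative. Two attribution conventions are
implemented and recorded in every output:

* `single_driver` (default): region `i` is the sole driver (`B = e_i`)
  steering the brain from rest to the uniform state `N^{-1/2} * 1`.
* `whole_brain_control`: all regions are driven (`B = I`) and region `i` is
  the unit target; the energy is the i-th diagonal entry of `W(T)^{-1}`.

The default deserves explanation, because the whole-brain convention is the
numerically easier one. With a zero-diagonal connectome, the whole-brain
energy has no linear term in `A` (its diagonal is zero) and its quadratic
term is `(A^2)_ii` with a *positive* coefficient, because the Gramian kernel
`g(lambda) = 2 mu / (e^{2 mu T} − 1)`, `mu = lambda − 1`, is convex. The
whole-brain energy is therefore locked anti-parallel to modal
controllability: any data feature that lowers `phi_i` raises that energy.
A regional profile in which average controllability rises while *both*
modal controllability and activation energy fall — the profile of interest
for hub strengthening — is structurally impossible under the whole-brain
convention on correlation-derived systems of this kind. The single-driver
convention attributes the energy to the region as an actuator, and a region
whose couplings strengthen genuinely needs less input energy to move the
brain; it reproduces the expected joint signature and is therefore the
default. The whole-brain convention remains available and fully tested.

Single-driver finite-horizon Gramians are severely ill-conditioned: the
energy contains `1 / u_j^2` factors, where `u = V' e_i` is the driver's
eigenmode loading, so modes the driver barely reaches dominate. The
implementation uses the exact factorization
`E_i = y' S^{-1} y`, `y = (V' x_f) / u`,
`S_jk = (e^{(mu_j + mu_k) T} − 1) / (mu_j + mu_k)`, which costs one
eigendecomposition per subject plus O(N^2) per region, and floors loadings
at `|u_j| >= 0.01` (the `loadingFloor` argument; the floored fraction is
returned as an attribute). The floor is a recorded regularization, chosen
small enough that well-conditioned small systems agree with the generic
pseudoinverse energy (`minTransitionEnergy`) to 1e-8 and large enough to cap
the dynamic range of the heavy upper tail. Raising it substantially (e.g.
to 0.3 / sqrt(N)) biases group contrasts toward zero and is not
recommended.

`minTransitionEnergy` itself follows the general definition: Gramian by the
block-matrix-exponential (Van Loan) construction, validated against
composite-Simpson quadrature at 1e-8; eigenvalue-truncated pseudoinverse
with the reachability residual `||(I − W W^+) v||` reported; a condition
number above 1e12 sets a warning flag in the result rather than failing.

## Aggregation, phenotype, inference, classification

Regional metrics are averaged, unweighted, to three levels: the whole
brain; eight "networks" (the seven cortical resting-state networks plus the
entire subcortex as one unit); and the seven subcortical nuclei. Unweighted
means are deliberate — no volume weighting — and aggregation is linear, a
property the tests assert directly.

Cognitive phenotyping computes per-domain means over a nine-subtest battery
mapped to four domains, a global score as the mean of the four domain means
(a mean of means, not a pooled subtest mean — the tests distinguish the
two), and the impairment status: at least two subtests at or below the
control mean minus 1.5 control SDs makes a patient CIMS; the boundary counts
as impaired. Control statistics come from the cohort's own controls, not
external norms. Subtests are averaged on their raw scale; all synthetic
subtests are higher-is-better, so no sign harmonization is needed.

Group inference uses Freedman–Lane residual permutation: the outcome is
regressed on the nuisance covariates (standardized age, sex as 0/1), the
reduced-model residuals are permuted and re-added to the reduced fit, and
the group-indicator t statistic of the full model is recomputed per
permutation. The p-value `(1 + #{|t*| >= |t|}) / (1 + n_perm)` has floor
`1/(n_perm + 1)`. Because permuting residuals leaves their sum of squares
unchanged, the whole permutation distribution reduces to one matrix product,
which is what makes 10,000 permutations across 192 tests cheap.
Benjamini–Hochberg FDR is applied within each (contrast, metric, level)
family — families of 8 at the network level and 7 at the nucleus level —
mirroring how multi-network scans are usually reported; family labels are
written into the output table. Chi-squared tests for sex ratios use the
Pearson statistic without continuity correction.

Classification uses linear SVMs (cost 1) under stratified 5-fold
cross-validation repeated 100 times by default, with features standardized
by training-fold statistics only (a leakage canary test guards this).
Decision values, not hard labels, feed the AUC. One deliberate departure
from the obvious default: classes are weighted inversely to their
training-fold frequencies. With 27 controls against 102 patients, the
unweighted linear SVM collapses onto the majority class (specificity near
zero) and — worse for a threshold-free metric — the *sign* of its
separating direction becomes numerically unstable across folds, corrupting
the decision-value AUC. Balanced weighting restores a stable direction and
a balanced sensitivity/specificity profile; unweighted fitting remains one
flag away (`classWeights = "none"`).

## The synthetic cohort generator

The real data this analysis style is applied to are not redistributable, so
the generator is a first-class, tested module that encodes the statistical
structure the analysis assumes, with known ground truth. Defaults define
the frozen study conditions: 27 HC / 47 CPMS / 55 CIMS subjects, 454
regions (400 cortical over seven networks, 54 subcortical over seven nuclei
with a 16-region thalamus), 100 timepoints.

**Dynamics.** Subjects evolve as a stationary Gaussian VAR(1),
`x_{t+1} = A x_t + eps`, isotropic unit-variance innovations, 300 burn-in
steps discarded. There is no hemodynamic convolution, no head motion, no
physiological noise: the analysis consumes only Pearson correlations, which
the VAR parameterizes cleanly, and testability was valued over realism.

**Coupling template.** The base coupling is a deterministic structured
skeleton individualized by a small multiplicative jitter (SD 0.02): a weak
global positive background (relative eigenweight 0.5), system-level blocks
(0.4), strong sub-blocks of about eight regions within each system (1.0;
0.3 within the thalamus), and focal positive thalamo-cortical projections —
each thalamic region projects onto one cortical sub-block, assigned
round-robin, with relative hub eigenweight 0.2 spread over 8 targets. The
matrix is scaled so its spectral radius is exactly 0.9. An early fully
random block design was abandoned: random skeletons produce occasional base
graphs whose thalamic response to the injected effect flips sign, which
makes parameter-recovery rates a property of the lottery rather than of the
method.

Two structural facts shaped this design and are worth recording. First,
for a symmetric VAR(1) with isotropic noise the stationary covariance is
`(I − A^2)^{-1}`: pairwise correlation responds to coupling only at second
order. At a spectral radius of 0.6 this leaves all correlation structure an
order of magnitude below the Pearson sampling noise of 100-timepoint
series, and no injected coupling effect of any size survives the pipeline —
the spectral radius must sit near instability (0.9) for the connectome to
carry recoverable structure, which also matches the strong correlations of
real resting-state data. Second, both the per-subject rescaling to a fixed
spectral radius and the per-node variance normalization of the Pearson
correlation cancel *amplitude* effects: a hub whose edges are simply
multiplied up gains little once its eigenvalue approaches the spectral
budget. Focal projections into correlated sub-blocks, kept sub-dominant in
the spectrum, are what lets a multiplicative effect propagate.

**Patient effect.** In patients, every thalamus-to-nonthalamus edge is
multiplied by `1 + effect` before individual noise (SD 0.002) and
rescaling; the defaults are 1.5 (CPMS) and 3.0 (CIMS). The magnitudes were
calibrated once, by dose-response sweeps over the template, so that group
effects are detectable at the study's sample sizes, and then frozen; they
are generator conventions, not claims about MS biology. Patients with EDSS
of 4 or more receive 1.25 times their group effect, those below 4 receive
0.75 times, so disability strata carry controllability signal while the
CIMS/CPMS EDSS distributions remain comparable.

**Phenotypes.** Thalamic volume is drawn at one SD below the control mean
in both patient groups — informative for MS vs HC, null between CIMS and
CPMS by construction. CIMS subjects have three randomly chosen subtests
suppressed by 2.5 control SDs; patients are drawn with half the control
within-group SD so that the 1.5-SD rule recovers the generative label in at
least 95% of patients (with control-sized dispersion the rule's false-CIMS
rate among preserved patients alone exceeds 10%, which would make the
generative labels unrecoverable by the rule that defines them). Ages are
truncated normal (HC mean 40, MS mean 45, SD 10, range 18–60); sex is
Bernoulli with 65% female in all groups; EDSS is a truncated normal around
4 rounded to half points, and generation fails loudly if a disability
stratum comes out empty.

**What passing tests show — and what they do not.** Recovery of the
injected effects demonstrates that the chain from coupling to VAR to
correlation to stabilized dynamics to Gramian metrics to permutation
inference is implemented correctly and has power at the study's sample
sizes under the generator's assumptions. It does not show that real MS
produces these effect sizes, that hemodynamics and motion would not erode
them, or that the thalamus-specific signature in real data arises from
coupling multiplication; the generator's mechanism was chosen to *produce*
the direction reported for real cohorts, so recovering that direction
validates the machinery, not the biology.

## Problem sizes and runtime

The test suite and the acceptance script run everything at sizes chosen to
keep a full run on one CPU within minutes: parameter-recovery loops use 129
subjects at 100 regions with 2,000 permutations over 20 generated cohorts;
null false-positive rates use 30-subject, 60-region cohorts over 50 seeds;
type-I calibration uses 1,000 null datasets with 999 permutations; the
classification panel runs at the full 454-region default scale, averaged
over three cohorts with 15 cross-validation repeats (the null volume AUC
has a Monte-Carlo SD near 0.06 on a single cohort, so averaging is variance
reduction, not a condition change). A full-scale end-to-end run (129
subjects, 454 regions, 10,000 permutations, 5x100 cross-validation) takes
on the order of ten minutes.

## Numerical conventions

* Symmetry is enforced at 1e-10 relative on inputs to stabilization and the
  metric functions; violations error rather than warn.
* Spectral radii are computed with the symmetric eigensolver whenever the
  matrix is symmetric to 1e-8.
* The generator's spectral-radius scaling is exact to floating point and
  asserted at 1e-9 by the class validity method.
* Gramian pseudoinversion truncates at `max(eigenvalue) * N * eps`;
  condition numbers above 1e12 set a warning flag in the result.
* Permutation p-values never reach zero (`(1 + k)/(1 + n)` form), and a
  constant outcome returns p = 1 with a warning.
* All randomness flows through per-purpose streams derived from one master
  seed; identical seed and specification reproduce cohorts byte-identically,
  and the RNG state of the caller is restored afterwards.

## Known limitations

* The VAR(1) generator has no hemodynamic forward model; its time series
  are more exchangeable than fMRI and its effective temporal degrees of
  freedom near the spectral radius of 0.9 are optimistic relative to
  scanner data at matched length.
* Single-driver energies have a heavy upper tail even with the loading
  floor; their group direction at reduced scale is right in roughly 17–19
  of 20 cohorts, not all 20, and the arithmetic unit means used for
  aggregation are outlier-sensitive.
* The EDSS classification task carries weaker signal than the cognitive
  contrast by design (the severity modulation is deliberately mild), so its
  AUC sits near 0.6 rather than the high values reported for real data.
* Whole-brain-convention activation energy cannot jointly reproduce
  "average up, modal down, energy down" on correlation-derived systems (see
  above); users who select it should expect energy to mirror modal
  controllability inversely.
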