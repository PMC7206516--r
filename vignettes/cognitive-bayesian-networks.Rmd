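---
title: "Hierarchical Bayesian-network modelling of a neuropsychological battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian-network modelling of a neuropsychological battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npbnet)
```

## The problem

Clinicians assessing dementia work from a battery of neuropsychological (NP)
tests — here eleven: three Logical Memory scores (LMi, LMd, LMr), three
Visual Reproductions scores (VRi, VRd, VRr), Paired Associate Learning with
its hard-pair variants (PASi, PASi_h, PASd_h), the Similarities test (SIM)
and the 30-item Boston Naming Test (BNT30) — plus an adjudicated cognitive
status: healthy control (HC), Alzheimer disease (AD) or non-Alzheimer
dementia (NAD). Scores are strongly correlated, patients frequently skip
tests, and a flat per-test analysis cannot say which cognitive functions
*precede* status changes and which are *consequences* of them.

`npbnet` models the battery and status jointly as a discrete Bayesian
network: a directed acyclic graph (DAG) over the 12 variables whose joint
distribution factorizes as

$$P(X_1, \dots, X_{12}) = \prod_v P(X_v \mid \mathrm{pa}(X_v)),$$

with one conditional probability table (CPT) per node. The DAG makes the
hierarchy explicit — upstream tests influence downstream ones, status both
receives and emits edges — and the CPTs turn any subset of observed scores
into a posterior over status by Bayes' theorem, so partially completed
batteries are handled without imputation.

## Pipeline

1. **Discretization** (`fit_discretization`). Each continuous score is
   clustered by exact one-dimensional k-medoids (PAM: greedy BUILD, then
   steepest single-swap descent on total absolute deviation). The number of
   intervals $k \in \{2,\dots,10\}$ is chosen by the mean silhouette width
   $\bar s = \mathrm{mean}_i\,(b_i - a_i)/\max(a_i, b_i)$, ties to the
   smaller $k$. Clusters become closed score intervals spanning each
   cluster's observed extremes.
2. **Correlation clusters** (`correlation_matrix`, `extract_clusters`).
   Pearson correlations on raw scores (pairwise-complete); cognitive-function
   clusters are the connected components of the graph thresholded at
   $r \ge 0.6$. Each test's association with status is screened by one-way
   ANOVA with Bonferroni correction over the 11 tests and Tukey–Kramer
   pairwise contrasts.
3. **Structure learning** (`hill_climb`, `tabu_search`,
   `bootstrap_average`). Search-and-score over DAGs with the BIC/MDL score
   $\sum_{jk} n_{jk}\log(n_{jk}/n_j) - \tfrac{\log N}{2}\, q\,(r-1)$ per
   family, hill-climbing over add/delete/reverse moves with cached family
   scores, tabu search as a cross-check, and nonparametric bootstrap model
   averaging: edges kept when their replicate frequency reaches the strength
   threshold, oriented by majority.
4. **Parameters** (`fit_mle`, `fit_bayes`). Relative-frequency CPTs, or the
   Dirichlet posterior mean $(n_{jk} + \mathrm{iss}/(rq)) / (n_j +
   \mathrm{iss}/q)$. Inference defaults to the Bayesian estimate with
   `iss = 1` because strictly positive CPTs keep importance weights
   well-defined.
5. **Markov blanket** (`markov_blanket`, `chi2_ci_test`,
   `blanket_sufficiency`). The status node's parents, children and spouses
   form the sufficient test subset $S$ with $P(\mathrm{Status}\mid G) =
   P(\mathrm{Status}\mid S)$; conditional-independence claims are screened
   by stratified Pearson chi-square tests with sparse-table-adjusted degrees
   of freedom.
6. **Inference** (`likelihood_weighting`, `averaged_inference`,
   `exact_posterior`, `predict_status`). Likelihood weighting clamps the
   observed tests and weights forward samples by the evidence likelihood;
   the clinical decision averages 100 repeats. An exact engine based on
   sum-product variable elimination serves as reference and powers the
   blanket checks.
7. **Evaluation** (`cross_validate`, `stratified_networks`). Status-stratified
   10-fold cross-validation of the whole pipeline (discretize, learn, fit,
   predict per fold) with a 3×3 confusion matrix, 3-class accuracy and
   dementia-vs-HC sensitivity/specificity, plus per-stratum (sex, ApoE4,
   education) network comparisons.

## The synthetic cohort generator

Cohort data of this kind are not freely redistributable, so the package
ships a first-class generator (`default_ground_truth`, `sample_cohort`)
whose defaults encode the study conditions the analysis assumes:

* **Status mix** (0.779, 0.123, 0.098) for HC/AD/NAD — the group sizes
  3514/555/443 of 4512 examinations.
* **Score profiles**: per-test, per-status normal distributions with the
  calibration means/SDs in `cohort_calibration()` (e.g. LMd 10.2±3.9 for
  HC, 3.0±4.0 for AD), discretized onto the score grid with tails absorbed
  at the range limits; PASi keeps its half-point grid.
* **Planted hierarchy**: SIM→BNT30→VRi→VRd→Status, plus
  Status→LMi→LMd→LMr, Status→PASi→PASi_h→PASd_h and Status→VRr. Chain CPTs
  are the conditionals of the status mixture; the Status|VRd table is
  calibrated by iterative proportional fitting so the network's exact
  status marginal equals the group proportions above.
* **Planted intervals**: near-equal-mass bins of each test's marginal
  (`n_bins = 5`; short-range tests get singleton bins). Equal-mass bins
  keep every CPT row well-populated, which is what makes parameter recovery
  at finite samples well-conditioned.
* **Participants**: exam counts are 1 + Geometric with mean 2.2; one status
  per participant; exam rows independent given status (the analysis treats
  each examination as a study sample, so within-participant correlation
  beyond shared status is deliberately not modelled).
* **Covariates** sex/ApoE4/education follow the status-conditional
  prevalences of the calibration table; they stratify analyses but are not
  network nodes.
* **Missingness**: scores (never status) are masked completely at random at
  rate 0.05.

What the generator does *not* emulate — and hence what passing tests cannot
show about real cohorts: age and practice effects, informative missingness,
within-participant trajectories, measurement floors/ceilings beyond the
score range, and any dependence between tests that bypasses status or the
planted chains. Conditional score distributions in the real battery are
also not mixtures of discretized normals. Results on the generator validate
the *machinery*, not clinical performance.

A consequence of generating through the planted chains: for tests reached
from status only through intermediate tests (e.g. LMd via LMi), the
status-conditional means are pulled toward the population mean relative to
the calibration table — the HC mean survives nearly unchanged (the HC group
dominates), while the AD tail is smeared. The directly status-driven tests
(LMi, PASi, VRr, and VRd through its calibrated CPT) keep their group
separation.

## Defaults and numerical choices

| Setting | Default | Why |
|---|---|---|
| `k_max` (intervals per test) | 10 | silhouette is undefined at $k=1$; ten intervals match the battery's score resolution |
| PAM ties | lower medoid / lexicographically smaller set | determinism; no rule is canonical |
| correlation cutoff | 0.6 | the conventional cut for "same cognitive function" in this battery |
| `use_abs` | FALSE | inter-test correlations in this battery are positive; flag available |
| score | BIC/MDL | penalizes the $q(r-1)$ free parameters per family; BDeu/AIC behind a switch |
| hill-climb restarts | 5 (standalone), 0 (inside bootstrap) | restarts escape ties; resampling already varies the bootstrap runs |
| tabu list / stagnation | 10 / 15 | short memory suffices at 12 nodes |
| bootstrap `B` | 500 standalone; 25 inside CV | conventional averaging default vs. per-fold budget |
| strength threshold | 0.5 | majority-vote edge retention |
| estimator | `fit_bayes`, `iss = 1` | zero-free CPTs for importance weighting |
| inference | 5000 samples × 100 repeats | matches the exact engine to total variation well below 0.02; CV predictions use 1000 × 20, which preserves the argmax |
| CV | 10 folds, status-stratified, fold-scoped discretization | every class in every training fold; no leakage through the interval map |
| binarization | dementia (AD∪NAD) vs HC | a 3-state outcome has no unique sensitivity/specificity; the AD-vs-rest variant is a config option |

Other numerical details: $0 \log 0 \equiv 0$ throughout; equal-score search
moves resolve in (from, to, move-type) order; unseen parent configurations
get uniform CPT rows (flagged); a bootstrap-averaged edge whose majority
orientation would close a cycle is dropped as the weakest edge of that
cycle; exact inference eliminates variables greedily by smallest
intermediate factor; `predict_status` breaks posterior ties toward HC (then
NAD) and flags them. Degenerate inputs fail loudly: constant columns in
discretization, out-of-range scores, impossible evidence (all importance
weights zero), cyclic graphs, classes too small for the fold count.

Design questions the method leaves open were resolved as follows: PAM runs
per variable (the interval maps are univariate); status passes through
discretization untouched; clusters are connected components rather than a
hierarchical cut; structure search is unconstrained by default (black/white
lists accepted); CV refits structure per fold; discretization scope defaults
to `fold` with `global` available; examination rows are the CV unit with
optional `group_by_participant`.

## Problem sizes

The test-suite and acceptance runs use cohorts of 4,500 examinations
(matching the calibration cohort's 4,512), 200 bootstrap replicates over 10
seeds for structure recovery under the generator's strong-dependence
setting (`sd_scale = 0.5`), 100,000 forward samples for parameter recovery,
5000×100 likelihood-weighting draws against exact posteriors on twenty
random 12-node models, and a full 10-fold cross-validation at the package
defaults. Each stage's seed derives deterministically from one master seed.

## Known limitations

* PAM's BUILD+SWAP is a local search: on adversarial small samples a strict
  swap-local optimum can sit above the global k-medoids optimum. On
  score-like data with separated modes the two coincide.
* BIC orients edges only up to Markov equivalence; chains without colliders
  (like the planted reasoning-to-visual chain) can be returned reversed.
  Bootstrap direction fractions quantify exactly this uncertainty.
* Likelihood weighting degrades when the evidence likelihood is tiny;
  `averaged_inference` reports per-repeat effective-weight diagnostics, and
  the exact engine is available whenever the state space allows.
* The conditional-independence p-values rely on the chi-square asymptotics
  within strata; the adjusted degrees of freedom correct for empty cells
  but not for small nonzero expected counts.
* No latent-variable learning, no parameter estimation from incomplete rows
  (complete-case per family), no causal claims beyond the Markov-blanket
  screen.
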