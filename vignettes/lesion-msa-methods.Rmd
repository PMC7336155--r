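---
title: "Multiperturbation Shapley value analysis of white-matter lesion data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiperturbation Shapley value analysis of white-matter lesion data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmsa)
```

## The inference problem

Classical lesion-symptom mapping asks, tract by tract, whether damage
correlates with a deficit. That univariate view cannot separate the
contribution of a tract from the contributions of its frequently
co-lesioned neighbours. `lesionmsa` instead treats the problem as a
coalition game: the *players* are the white-matter bundles of interest
(by default eleven right-hemisphere tracts — the three branches of the
superior longitudinal fasciculus, the inferior fronto-occipital and
inferior longitudinal fasciculi, the corpus callosum, the anterior
thalamic projections, the optic radiations, the posterior arcuate
segment, and the anterior and posterior cingulum) plus a compound
*rest of brain* (RoB) player covering all remaining white matter. The
*worth* of a coalition is the performance the system achieves on a
neuropsychological task when exactly the players in the coalition are
intact and the rest are perturbed. A player's causal contribution is its
Shapley value

$$\phi_i \;=\; \sum_{S \not\ni i}
  \frac{|S|!\,(M-|S|-1)!}{M!}\,
  \bigl[v(S \cup \{i\}) - v(S)\bigr],$$

the average marginal contribution of player $i$ over all orderings in
which players can join the coalition. The Shapley value is the unique
allocation satisfying efficiency
($\sum_i \phi_i = v(\text{all}) - v(\emptyset)$), symmetry, the dummy
axiom and additivity; these axioms are enforced exactly by
`exact_shapley()` and checked property-style in the test suite. A
*positive* contribution means damage to the tract predicts worse task
performance; a *negative* contribution means damage paradoxically
predicts better performance. Pairwise interaction terms are deliberately
not computed for white-matter players.

## From lesions to a graded dataset

**Disconnection metric.** Each patient's binary lesion mask (already
registered to the atlas grid; registration is out of scope) is
intersected with each tract's binarized probability map:

$$d(\text{lesion}, \text{bundle}) =
  \frac{\#(\text{lesion} \cap \text{bundle})}{\#\text{bundle}},$$

with voxels counted unweighted, matching the set-cardinality form of
the metric. The *intactness* used everywhere downstream is $1 - d$, so
0 codes complete damage and 1 complete preservation. The atlas
binarization threshold defaults to 0.5 and is configurable; thresholding
at 0.5 is the natural reading of "binary segmentation" when no value is
stated. For the RoB player, the region is the union of the pool (non-
player) tract maps *minus* any voxel that also belongs to a player
tract, so shared voxels are never double-counted against the RoB; the
alternative (keeping the overlap) is a defensible reading, but the
exclusion makes the RoB fraction independent of the players by
construction.

**Behavioral binarization.** Clinical cut-offs binarize each test:

* *line bisection* — mean deviation over 20 cm lines, converted from the
  tabulated percent to mm as $\text{mm} = \text{pct}/100 \times 200$;
  pathological when strictly $> +6.5$ mm or strictly $< -7.3$ mm;
* *bells cancellation* — right-minus-left found bells (15 per side);
  pathological when $|\text{score}| > 2$;
* *letter cancellation* — right-minus-left *omissions* (30 targets per
  side); pathological when $|\text{score}| > 2$.

All inequalities are strict ("larger than" read literally), so boundary
values classify as normal. The age-conditional letter norms collapse to
the single $|\cdot|>2$ rule actually applied to this cohort. Because the
game needs an *ability* score, the deficit coding is inverted:
performance $= 1 -$ deficit. Patients missing a test are excluded from
that test's subcohort inside the pipeline — never by pre-filtering
files — which reproduces the 23/24/19 completion pattern of the
reference cohort.

## The estimated MSA

With $M = 12$ players there are $2^{12} = 4{,}096$ perturbation
configurations but only $\sim 25$ patients, so the characteristic
function cannot be observed; it is *predicted*. A support vector machine
(C-classification, SMO-class solver, box constraint $c = 1$) is trained
on the original-graded dataset — patients' intactness vectors in
$[0,1]^M$ against binary performance — and then queried at binary
configurations. Feature scaling is disabled so graded patient vectors
and binary configurations live on the same scale; a patient vector that
equals a binary configuration receives the same label through either
prediction path (tested). Kernels follow the per-test choices: linear
for line bisection, polynomial for bells, quadratic for letter
cancellation, where *quadratic* means polynomial degree 2 and
*polynomial* defaults to degree 3 (the common library default); both
degrees are configurable and `kernel_scan()` reproduces the kernel
sensitivity analysis.

Shapley values are then estimated by uniformly sampling player
orderings (default 1,000): in each ordering every player receives its
marginal contribution $v(\text{predecessors} \cup \{i\}) -
v(\text{predecessors})$ with all not-yet-entered players perturbed.
This is an unbiased estimator; its per-player standard error is the SD
of the marginals over orderings divided by $\sqrt{n_\text{perms}}$.
Internally, configurations are memoised by bitmask key, so an analysis
touches each distinct configuration at most once — for 12 players a
whole 1,000-permutation run costs at most 4,096 predictor evaluations,
which also makes exact enumeration (`exact_shapley()`) cheap enough to
serve as a within-suite oracle for the estimator.

**Bootstrap.** Robustness and uncertainty come from resampling patients
with replacement (default 1,000 resamples at the original size),
retraining the predictor and re-estimating contributions each time.
Resamples whose labels collapse to a single class are redrawn (capped
at 100 attempts, counts logged) so the number of resamples stays fixed.
Two dispersion summaries are reported because they answer different
questions: `sd_boot`, the SD of mean contributions across resamples
(sampling uncertainty of the cohort), and `se_perm`, the mean
permutation-sampling SE (estimator noise). Significance is flagged when
the central $(1-\alpha)$ bootstrap percentile interval excludes zero
(default $\alpha = 0.05$); significance of MSA contributions is stated
in this literature without a test being named, and the percentile
interval is the standard nonparametric choice. Contributions are
normalized by the sum of their absolute values — signs preserved,
$\sum_i |\tilde\phi_i| = 1$ — so magnitudes compare across tasks;
dividing by $v(\text{all}) - v(\emptyset)$ is offered as an alternative
mode. Players significant with the same sign in every task are
*task-invariant* (positive or negative); all others are
*task-dependent*, with per-test signed patterns reported. The RoB player
takes part in every coalition but is excluded from the classification
table by default, since it is a diagnostic against omitted contributors
rather than an anatomical hypothesis.

**Chance level.** The permutation chance level mirrors the
leave-one-out loop: each held-out case is scored against the label of a
uniformly drawn *other* case, and agreement is averaged over
repetitions (default 1,000). This converges to
$\sum_k n_k(n_k-1)/\bigl(n(n-1)\bigr)$ for class counts $n_k$, which
`chance_level_exact()` computes in closed form. (A whole-vector shuffle
compared position-wise would instead converge to $\sum_k n_k^2/n^2$;
the leave-one-out reading is the one consistent with the closed form
and with the validation procedure it accompanies.) Predictor validity
is summarized by leave-one-out accuracy and the Youden index
(sensitivity + specificity − 1); degenerate single-class training folds
fall back to the majority class with a warning.

## The synthetic cohort generator

No lesion imaging is distributed with the reference cohort, so every
downstream stage is validated against synthetic studies with known
ground truth (`make_cohort()`, `make_fixture()`):

* **Atlas** — each tract is a compact Gaussian-profile blob with
  probability 1 at its core voxel. Cores sit on a lattice with at least
  twice as many cells as blobs, chosen by greedy farthest-point
  selection and jittered, so supra-0.5 cores are distinct and overlap by
  less than half. Extra blobs form the non-player pool behind the RoB
  region.
* **Lesions** — contiguous blobs grown by randomized 6-connected region
  growing from a uniform seed voxel; extents are log-normal with median
  1.5% of the grid volume. This size keeps pairwise inter-tract damage
  correlations low (mostly below 0.5 at large $n$, matching the largely
  independent lesion patterns reported for the real cohort), though
  occasional adjacent-core pairs can exceed that figure in a given
  draw.
* **Behavior** — the generative model is deliberately the minimal one
  under which contributions have known sign and rank: latent performance
  $= \sum_i w_i\,\text{intact}_i + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$ (default $\sigma = 0.25$), a label
  is normal when the latent reaches a threshold (default: the cohort
  median of the noiseless latent, balancing classes), and raw test
  scores are synthesized *consistently with* the binary outcome, so
  re-scoring the patient table through the clinical cut-offs reproduces
  the generated labels exactly (tested). Default weights are signed with
  descending magnitudes and a small RoB weight.
* **Missingness** — injected completely at random per test with
  configurable counts defaulting to 2/1/6 missing of 25 (the 23/24/19
  completion pattern); a patient is never removed from all three tests
  at once unless configured.

Everything is a pure function of its arguments including the seed.

What passing tests on these cohorts show — and do not show: they
demonstrate that the estimator chain (disconnection → SVM → sampled
permutations → bootstrap) recovers the signs and ranks of a known
linear-threshold mapping at $n = 200$ patients, and that all axioms and
metrics are computed correctly. They do not show that real lesion
anatomy is well approximated (blob lesions have no vascular-territory
structure), nor that recovery succeeds at $n \approx 25$: at the
reference cohort's size the bootstrap dispersion is large and per-test
validation statistics vary widely between draws, which is precisely why
the published headline accuracies cannot be checked without the
original imaging.

## Numerical choices and degenerate inputs

* Exact enumeration is limited to $M \le 20$; the coalition weights
  $|S|!(M-|S|-1)!/M!$ are computed via `lfactorial` for stability.
* Bitmask keys are exact in doubles up to $M = 50$; beyond that the
  memoisation refuses rather than silently degrading.
* Zero-variance tracts make correlation entries undefined; they are
  flagged and reported, never silently zeroed. Cohorts of fewer than 3
  patients are rejected for correlations, fewer than 3 for
  leave-one-out.
* A single-patient summary reports SD as missing rather than 0; the SD
  denominator is $n-1$ throughout (the convention that reproduces the
  reference cohort's printed dispersion).
* All-zero contribution vectors cannot be normalized and raise an
  error; bootstrap intervals from fewer than 20 resamples are flagged
  unreliable.
* Problem sizes used by the test suite and the acceptance script —
  synthetic validation cohorts of $n = 200$ patients on a $16^3$ grid
  with 11 tracts + 4 pool tracts, 1,000 sampled orderings, 100
  bootstrap resamples for recovery checks, and the full 1,000 × 1,000
  setting for the 25-patient end-to-end fixture — were chosen so each
  check is statistically informative at a desk-scale runtime.

## Known limitations

* The artifact consumes masks already in atlas space; bias correction,
  enantiomorphic filling and diffeomorphic registration are upstream
  concerns, as is manual lesion delineation.
* Probability-weighted (rather than binarized) tract overlap is not
  implemented; the set-cardinality metric is the form adopted.
* The SVM predictor extrapolates from ~25 graded patterns to all
  binary configurations; contributions inherit any bias of that
  extrapolation, which the bootstrap quantifies only partially.
* Per-patient binary classifications for the reference cohort are not
  published, so row-level agreement of the binarization with the
  original coding cannot be verified; the subcohort sizes (23/24/19)
  are the checkable consequence and are reproduced exactly.
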