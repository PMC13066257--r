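---
title: "Mapping seizure frequency to tumor location: methods and design"
author: "glioVLSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping seizure frequency to tumor location: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Low-grade gliomas (LGGs) are strongly epileptogenic, and how often a
patient seizes matters clinically: frequent seizures degrade quality of
life, complicate surgery, and predict worse post-operative seizure
control. Whether some brain locations make a tumor more likely to cause
*frequent* seizures — rather than merely seizures at all — is a question
about voxels, not lobes. `glioVLSM` implements voxel-based lesion-symptom
mapping (VLSM) for exactly this setting: a cohort of binary tumor masks
registered to a common template grid, paired with an ordinal
seizure-frequency score and clinical covariates.

## The voxel-wise model

At every voxel the package fits the general linear model

$$ Y = X\beta + \varepsilon $$

with the **binary lesion indicator as the response** \(Y\) (1 = the
subject's tumor covers the voxel, 0 = tumor free) and the symptom matrix
\(X\) as predictors — a linear-probability model per voxel. The columns
of \(X\) are, in order:

1. the ordinal seizure-frequency score (0 = no seizure history, 1 = only
   one or two seizures ever, 2 = more than once per month, 3 = more than
   once per week, 4 = more than once per day),
2. sex (male = 1, female = 0),
3. age in years,
4. tumor volume in cm³,
5. an intercept.

The reported statistic is the \(t\)-value of the frequency-score
coefficient with \(n - p\) residual degrees of freedom; the three
nuisance columns regress the covariate effects out of the map. This
response/predictor orientation (lesion status as \(Y\)) is deliberate:
it treats the symptom score as the design and asks where lesion presence
tracks it. Nuisance columns are mean-centered, which leaves the
frequency \(t\) unchanged (an invariance the test suite verifies at
1e-8) but keeps the intercept interpretable as a baseline lesion
probability. The score enters as a numeric 0–4 variable, honouring the
ordinal grading directly rather than expanding it into indicators.

Two degenerate situations are handled explicitly. Voxels whose lesion
indicator is constant across subjects carry no information and are
marked ineligible. Voxels fit with zero residual (the lesion indicator
is an exact linear function of the design) have an infinite nominal
\(t\); the package caps it at the largest finite double and flags the
voxel as a deterministic fit, so downstream thresholding still works.

## Where can the model speak at all? Overlap and power

A voxel lesioned in 2 of 352 subjects cannot support inference. The
lesion-overlap map counts, per voxel, the subjects whose mask covers it;
from the split of \(k\) lesioned versus \(n-k\) spared subjects a
per-voxel statistical power is computed for a fixed standardized
two-sample difference \(d\):

$$ \mathrm{power}(k) = \Phi\!\left(d\sqrt{\tfrac{k(n-k)}{n}} -
   z_{1-\alpha/2}\right), $$

set to 0 where \(k \in \{0, n\}\). Voxels with power **strictly** above
0.8 (at \(\alpha = 0.05\)) form the eligible set; the power screen runs
*before* the permutation stage, so the null distribution is only built
where the result could be trusted. The assumed effect size defaults to
\(d = 1.0\) — a large single-voxel effect appropriate for screening —
and is configurable; the threshold 0.8 is the conventional adequacy
cutoff. Because \(k(n-k)\) is maximized at \(k = n/2\), the screen is
simply a band of acceptable lesion counts.

## Permutation thresholding

Parametric \(t\) thresholds are untrustworthy for a binary response, so
voxel-wise thresholds come from permutation. Under the default
`"score"` scheme only the frequency-score column of \(X\) is permuted
across subjects; sex, age and tumor volume stay attached to their
subject's lesion. This is the minimal exchangeability assumption — the
symptom is shuffled, the lesion-covariate dependence is preserved. A
Freedman–Lane scheme (permute the lesion residuals after regressing out
the nuisance columns) is available as an option for users who prefer
full nuisance-orthogonalized permutation; on the synthetic cohorts the
two give closely similar thresholds.

With \(B\) permutations the per-voxel threshold is the
\(\lceil (1-\alpha) B \rceil\)-th order statistic of that voxel's
permuted \(t\)-values (\(B = 1000\), \(\alpha = 0.05\) by default, i.e.
the 950th of 1,000). A voxel is retained exactly when it is eligible and
its observed \(t\) is **strictly greater** than its own threshold — it
beats more than a \(1-\alpha\) fraction of the permuted statistics. The
test is one-sided: only positive lesion-frequency associations are kept.
Thresholding is voxel-wise by design (each voxel is compared with its own
null); a max-statistic familywise mode (`mode = "max_stat"`), which takes
the same order statistic of the permutation distribution of the
image-wide maximum \(t\), is exposed for users who want FWE control, and
the suite checks it is conservative on null cohorts.

One consequence of the empirical order-statistic definition is worth
stating: with \(B = 200\) and strict `>`, the retention probability of a
null voxel is exactly \(11/201 \approx 0.055\), not 0.05 — the
discreteness of the empirical quantile, not a bug. The calibration test
accounts for this.

All permutation work is a pure function of an explicit integer seed;
stochastic entry points have **no default seed** and refuse to run
without one.

## Clusters, peaks, and involvement

Retained voxels are decomposed into maximal connected components under
26-neighborhood connectivity by default (6 and 18 are available);
26-connectivity is the common choice for volumetric lesion data. Each
cluster reports its size and peak (highest-\(t\)) voxel; clusters are
sorted by peak \(t\) descending and all ties — within a cluster and
between clusters — break to the lexicographically smallest coordinate,
making the output fully deterministic. Coordinates are 0-based
internally and reported alongside 1-based indices, so they can be
compared with template-space conventions without silent off-by-one
errors.

A subject is *involved* at a peak when their tumor mask contains the peak
voxel. The package then compares frequency scores between involved and
non-involved subjects with a Mann–Whitney U test, optionally restricted
to one hemisphere's subjects.

## Clinical statistics

The accompanying cohort statistics follow the reporting conventions of
the surgical-epilepsy literature:

* **Pearson chi-square without continuity correction** for categorical
  group comparisons. The choice matters: with Yates correction the
  reference cohort's resection-by-frequency table gives p ≈ 0.012; the
  uncorrected statistic reproduces the published 0.008.
* **Mann–Whitney U** with midranks and the tie-corrected normal
  approximation (no continuity correction) for age, tumor volume and the
  heavily tied ordinal scores; exact enumeration is pointless under this
  many ties.
* **Multivariate logistic regression** (maximum likelihood, Wald
  inference, odds ratios with 95% CIs) over predictors passing the
  univariate screen at strictly p < 0.05. Non-convergence and
  (quasi-)separation are flagged and coefficients withheld.
* p-values print to three decimals, values below 0.001 as `<0.001`.
* The surgical outcome (Engel class) is dichotomized as Class I
  (seizure free) versus Classes II–IV (uncontrolled); a missing class
  silently excludes the subject from outcome analyses.

`referenceCohortTables()` carries the printed, fully recomputable
contingency tables of a published 352-patient LGG cohort;
`referenceCohort()` reconstructs a subject-level table matching those
margins exactly. Only margins are published, so variables are assigned
independently within frequency groups: every per-variable group
comparison is exact, any joint (multivariable) statistic on the
reconstruction is synthetic, and its continuous columns are deterministic
fillers, not data.

## The synthetic cohort generator

No patient images are distributed with (or required by) the package, so
validation rests on a generator that emulates the statistical structure
the model assumes:

* **Lesions** are connected blobs: the \(k\) voxels nearest a uniformly
  sampled centre under a randomly anisotropic ellipsoidal metric, where
  \(k\) matches a volume drawn from Normal(80.8, 60.0) cm³ clamped below
  at 1 cm³ — the scale reported for surgical LGG cohorts. Clamping (an
  atom at 1 cm³) rather than resampling keeps the mean near the target.
* **A hidden epileptogenic ROI**: a sphere of radius 3 voxels near the
  grid centre. Each subject's involvement fraction is
  \(|lesion \cap ROI| / |ROI|\).
* **An ordinal latent model**:
  \(\text{latent} = \gamma \cdot \text{frac} + \beta^\top(\text{covariates}
  - \overline{\text{covariates}}) + \varepsilon\), with
  \(\varepsilon \sim N(0, 1)\), cut at four fixed thresholds into the
  five frequency categories. The cut points are calibrated
  (`qnorm(c(.301, .642, .855, .926))`) so that a *null* cohort
  (\(\gamma = 0\)) reproduces the reference cohort's category mix —
  roughly 30% no seizure, 34% rare, 21% monthly, 7% weekly, 7% daily.
* **Covariates**: age ~ Uniform(16, 68), 60% male, volume taken from the
  realized lesion; small non-zero latent coefficients for all three so
  the nuisance regression has something to remove. Categorical clinical
  fields (seizure type, ASM use, resection, pathology, Engel class) are
  drawn with marginals typical of such cohorts; hemisphere and a coarse
  lobe label come from the lesion geometry.

The default planted effect is \(\gamma = 5\) latent standard deviations
at full ROI coverage. This is deliberately strong: the generator's
default configuration is meant to be a *positive control* in which the
mapping should recover the ROI reliably. With blob lesions roughly seven
voxels in radius against a three-voxel ROI, lesion status at voxels just
outside the ROI is almost as predictive of involvement as status inside
it; at moderate effect sizes (\(\gamma \approx 3\)) the top peak lands a
voxel or two outside the ROI boundary in ~20–25% of cohorts, a geometric
displacement inherent to lesion data, not an estimation failure. At
\(\gamma = 5\) the peak falls inside the ROI in ≥ 90% of seeds at
n = 60. Users studying sensitivity should sweep \(\gamma\) down
themselves.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: brain-shaped support and
anatomical lesion predilection (tumors prefer particular lobes), growth
and infiltration patterns, registration and segmentation error,
between-variable clinical correlations beyond those induced by the
latent model, and ASM effects on the observed frequency. The pipeline's
statistical calibration and recovery behaviour transfer; anatomical
realism does not.

Everything is a pure function of the `SimulationConfig`, seed included:
identical configs give bit-identical cohorts, which the suite checks at
the byte level on disk.

## Numerical and design choices

* Float masks binarize at 0.5 (masks resampled with interpolation arrive
  fractional); only nearest-neighbor grid resampling is offered —
  registration is upstream of this package.
* The grid is fully configurable because reported template resolutions
  and coordinate conventions vary; the package never assumes a
  particular template.
* All subjects, including those with no seizure history (score 0), enter
  the VLSM by default — the score scale explicitly includes 0; a
  seizure-only analysis is a flag away.
* Residual tolerance for declaring a deterministic fit: rss < 1e-10·n.
* `sort.int(partial = k)` order statistics per voxel keep the
  permutation stage O(V·B) in memory and fast in practice (about a
  second for 1,000 permutations over ~2,600 eligible voxels at n = 60).

## Problem sizes used by the test suite

The suite runs entirely on synthetic data at desk scale, the package's
own choice of problem size: a 24×28×24 grid at 4 mm for pipeline and
recovery checks (20 seeds, n = 60, 1,000 permutations), a 16³ grid at
6 mm with a power screen at d = 2 for the 200-cohort null-calibration
study (n = 40, 200 permutations each — d = 2 keeps the eligible set
usable at that cohort size), and exhaustive 6!-permutation enumeration
against an independent `lm()` oracle for the threshold's order-statistic
semantics. The method is resolution-agnostic, so nothing in these sizes
is load-bearing beyond runtime.

## Known limitations

* A linear-probability model per voxel is the stated design; it is not a
  logistic lesion model, and its \(t\) is only calibrated through the
  permutation stage, never parametrically.
* Voxel-wise thresholding controls the per-voxel rate, not familywise
  error; use `mode = "max_stat"` for FWE.
* Peak-based involvement reduces a cluster to one voxel; subjects
  lesioned throughout a cluster but missing the peak count as
  non-involved.
* The multivariate screen inherits every known fragility of
  significance-gated model building; it is provided because it is the
  field's reporting convention.
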