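---
title: "Decoding task conditions from functional-connectivity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding task conditions from functional-connectivity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fcmvpa` implements multivariate pattern analysis on task-fMRI functional
connectivity (fcMVPA): instead of asking which regions *activate* differently
across experimental conditions, it asks whether the pattern of temporal
correlations between region-of-interest (ROI) time series carries enough
information to classify the condition a subject was experiencing. This
vignette is the package's account of the method, its assumptions, the choices
made where the design was genuinely open, and what the simulation-based tests
do and do not establish.

## The model and the pipeline

The unit of analysis is the per-subject, per-condition connectivity map. For
a parcellation with $N$ nodes, the map is the $N \times N$ matrix of Fisher-z
transformed Pearson correlations,

$$ z_{ij} = \operatorname{atanh}(r_{ij}), $$

computed over the scans attributable to one condition, pooled across runs.
Because the matrix is symmetric, the strict lower triangle provides
$N(N-1)/2$ edge features; with the canonical 246-node whole-brain
parcellation this is $246 \times 245 / 2 = 30{,}135$ features. The pipeline
is:

1. **Denoising** (`denoise_subject()`): per run, each ROI series is
   residualised by ordinary least squares on a confound model — intercept,
   six head-motion parameters, nuisance components standing in for
   white-matter/CSF principal components, a first-order linear trend, and
   one HRF-convolved boxcar regressor per condition (so residual
   correlations reflect connectivity, not shared stimulus-evoked
   co-activation). Residuals are then band-pass filtered to 0.01–0.1 Hz.
2. **Condition scan attribution** (`condition_scan_indices()`): a scan
   belongs to a condition when that condition's HRF-convolved regressor is
   positive (above $\tau = 10^{-6}$) *and* maximal across conditions. The
   positivity-only rule would let the haemodynamic tail of one block bleed
   into the next block's scans; the argmax tie-break guarantees disjoint
   per-condition scan sets.
3. **Connectivity** (`fc_map()`, `feature_array()`): Pearson correlation
   over the pooled scans (pooled across runs, not averaged per run),
   clipped to $\pm(1-10^{-7})$ before `atanh`, diagonal fixed at 0.
4. **Decoding** (`loocv_decode()`): leave-one-subject-out cross-validation.
   In each fold, feature selection is fitted on the training subjects only;
   a linear soft-margin SVM (LIBSVM via `e1071`, cost 1) is trained per
   class pair on the selected edges; the held-out subject's maps are
   classified by one-against-one majority vote.
5. **Inference** (`permutation_test()`): condition labels are shuffled
   within each subject and the *entire* pipeline from selection onward is
   rerun per permutation; the observed accuracy is referred to this null
   distribution.
6. **Networks** (`consensus_mask()`, `top_k_network()`,
   `emotion_preferring_network()`): edges selected in *every* fold form the
   consensus set; each consensus edge's discriminative weight is the mean of
   its absolute SVM coefficients across folds; the top-50 edges form the
   discriminative network for a contrast, and the intersection of the two
   contrasts involving one condition forms that condition's preferring
   network.

## Feature selection

The primary selector (`positive_union_mask()`) keeps edges whose
connectivity is *significantly positive* in at least one condition: a
one-sample t test across training subjects per edge and condition, gated by
$t > 0$, corrected by Benjamini–Hochberg FDR at $q = 0.01$, with the final
mask the union over conditions. The restriction to positive connectivity
reflects the unsettled interpretation of negative BOLD correlations.
An alternative selector ranks edges by an F score — the two-class Fisher
criterion $((m_+ - m)^2 + (m_- - m)^2)/(s_+^2 + s_-^2)$, or the one-way
ANOVA F for three or more classes — and keeps the top $k$. By default $k$
equals the size of the positive-FDR mask on the same fold, which makes the
two selectors directly comparable; a fixed $k$ can be supplied instead.
`accuracy_curve()` traces accuracy as a function of the number of features
when edges are ranked by ascending one-sample-t p value.

Three choices here were genuinely open and are resolved as follows:

* *Sidedness.* "Significantly positive" is implemented as the two-sided p
  gated by $t > 0$ (the conservative reading); `one_sided = TRUE` switches
  to halved one-sided p values.
* *Pairwise masks.* Pairwise decoding pools positivity over the two classes
  in the pair (not all three); the union over the classes actually being
  discriminated is the self-consistent reading, and it keeps pairwise runs
  independent of conditions they never see.
* *Tie-breaking.* One-vs-one vote ties are broken by the class with the
  largest summed signed decision value, then by alphabetical class order.
  Decision-value sums almost never tie exactly, so the lexical rule is a
  formality that keeps the procedure deterministic.

## The synthetic cohort generator

No acquired data ship with the package, so every downstream stage is
exercised against a generator (`simulate_subject()`, `simulate_cohort()`)
whose ground truth is known:

* **Design** (`make_design()`): the default paradigm is three runs of 18
  blocks (3 emotions × 3 stimulus types × 2 repetitions) at TR = 2 s, each
  block 8 trials of 2 s stimulus + 0.5 s ISI (20 s), preceded by 10 s
  fixation and followed by a 2 s button-response interval, ordered so that
  neither the same emotion nor the same stimulus type appears in
  consecutive blocks. The order is found by randomised backtracking;
  exhausting the search proves a constraint set unsatisfiable. With a
  single stimulus type, the type constraint is vacuous (a single level
  cannot alternate) and only the emotion constraint is enforced.
* **Signal**: per scan, the latent ROI vector is drawn from a multivariate
  normal. During scans attributed to a condition the covariance is the base
  matrix plus that condition's edge-wise correlation increments; during
  rest it is the base matrix. This "covariance switching" produces exactly
  the kind of condition-specific correlation difference the estimator is
  built to detect, with known injected edges for recovery tests. Perturbed
  matrices that leave the positive-definite cone are shrunk back toward
  the base matrix (or rejected, naming the condition).
* **Base covariance** (`make_base_covariance()`): a two-factor model with
  positive loadings, giving all-positive, moderately heterogeneous
  correlations with mean $r \approx 0.35$–0.4. This matters: zero-phase
  band-pass filtering to 0.01–0.1 Hz leaves roughly a third of the Nyquist
  band, so the effective number of independent scans — and with it the
  precision of each edge estimate — is several-fold smaller than the scan
  count. With realistically strong positive base connectivity the
  positive-FDR selector retains a substantial edge set at desk-scale sample
  sizes, as it does on real data; with weak base connectivity the selection
  would be empty and the pipeline degenerate.
* **Confounds**: six motion traces as Gaussian random walks (step SD 0.02,
  giving per-run excursions of order 0.1–0.3 mm/degrees, matching typical
  compliant-subject head motion), coupled into the ROI signal with random
  coefficients; five smooth AR(1) nuisance components with per-ROI
  loadings; a per-ROI linear drift; white thermal noise (SD 0.3 against a
  unit-variance latent signal). The exact motion and nuisance traces are
  returned as the subject's confound matrix, so the confound-regression
  stage is exact in expectation — deliberately, since estimating nuisance
  components from tissue masks is out of scope.
* **Activation**: per-condition HRF-convolved amplitude gains are supported
  (and removed again by the task regressors during denoising) but default
  to zero.
* **Between-subject variability**: the generator exposes
  `subject_effect_sd`, a multiplicative SD on the injected deltas,
  defaulting to 0. This is the package's choice, not an empirical value:
  with the desk-scale cohort sizes used in the tests, a nonzero default
  would only inflate variance without changing what the tests establish.

What the generator does *not* emulate: voxel-level structure (all in-scope
computation operates on ROI means), scanner physics, spatially structured
artefacts, global-signal fluctuations, or heavy-tailed motion (no scrubbing
is implemented). Passing tests therefore establish the *procedure's*
correctness and calibration — selection without peeking, a permutation null
centred on chance, nominal type-I error, recovery of injected effects —
not performance claims on acquired fMRI data.

## Numerical choices

* Correlations are clipped to $\pm(1 - 10^{-7})$ before `atanh`, so
  duplicated series give a large finite z rather than infinity;
  zero-variance ROIs get $r = 0$ with a warning; map diagonals are 0 by
  convention and never enter the feature space.
* Edge order is the row-major strict lower triangle, fixed by
  `edge_index()`; every mask, weight vector and network maps back to node
  pairs through it.
* The band-pass filter is a fourth-order Butterworth applied
  forward-backward (zero phase, squared magnitude). Series are demeaned
  before filtering; DC is outside the pass band by definition and removing
  it first avoids start-up transients. Attenuation is $\ge 20$ dB one
  octave outside the band; in-band amplitude is preserved within 10%.
* Runs are denoised separately (no concatenation before filtering), which
  avoids filter transients at run boundaries; scan pooling happens only at
  the correlation stage.
* The degenerate one-sample-t cases are defined explicitly: zero variance
  with zero mean gives $t = 0, p = 1$; zero variance with nonzero mean
  gives a signed infinite t with $p = 0$, flagged.
* The permutation p value defaults to the add-one rule
  $(1 + \#\{A_{null} \ge A_{obs}\})/(B + 1)$, which is valid for any $B$
  and never zero; `rule = "strict_paper"` provides the strict-exceedance
  count $\#\{A_{null} > A_{obs}\}/B$ for comparability with the literature
  convention.
* Cross-validation reruns feature selection inside every permutation.
  Freezing the selection would be cheaper but optimistic; the conservative
  choice is the leakage-free one.
* The SVM cost is fixed at 1 (the LIBSVM default) with no inner tuning
  loop; weights are oriented so that a positive decision value predicts
  the alphabetically first class of each pair.

## Problem sizes in the tests

The calibration checks use sizes chosen once for desk-scale runtime and not
revisited: the permutation-null checks use 12 subjects × 60 ROIs (1,770
edges) with 99 label shuffles; the type-I-error check uses 200 replicate
null cohorts of 8 subjects × 24 ROIs with 49 shuffles each; the recovery
check uses 20 subjects × 60 ROIs over a full three-run session with +0.4
correlation injected on 20 vertex-disjoint edges (disjointness keeps the
perturbation's spectral norm at 0.4, inside the positive-definite cone, so
the planted effect needs no repair). The null checks use a reduced
single-stimulus-type design (2 runs × 3 emotions × 2 repetitions) with the
full default block timing. The 246-node feature-space
checks are structural and run at full parcellation size.

## Known limitations

* ROI time series and confounds are taken as given; no image-space
  preprocessing, nuisance-component estimation, or motion scrubbing.
* Unweighted scan pooling: scans within the attribution window contribute
  equally regardless of regressor amplitude.
* No partial-correlation or tangent-space connectivity; no nonlinear
  kernels; no probability calibration; no graph metrics beyond node degree
  in the export.
* The permutation test's granularity is limited by the prediction count;
  with small cohorts the discrete accuracy distribution makes the test
  mildly conservative at $\alpha = 0.05$.
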