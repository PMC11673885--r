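---
title: "Counting retinal microvascular lesions and grading diabetic retinopathy severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting retinal microvascular lesions and grading diabetic retinopathy severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drquant)
```

## The problem

Diabetic retinopathy (DR) is graded on the ICDR scale — no DR, mild,
moderate and severe non-proliferative DR — by qualitative inspection of
fundus photographs.  The grade boundaries are broad: two eyes at the
same level can differ substantially in microvascular burden.  Counting
the individual lesions visible in a single macula-centered fundus
image — microaneurysms (MA), hemorrhages (Hma), their union as red
lesions (RL = MA + Hma) and hard exudates (HE) — turns the grade into a
number, which makes progression within a grade measurable and supports
automated severity classification.

`drquant` implements the analysis half of that program.  Its input is
not the photograph but the *per-lesion binary segmentation masks* that
grading pipelines and public datasets provide (one raster per lesion
class per image), plus a manifest mapping images to datasets and ICDR
grades.  From there it counts lesion instances, filters unreliable
records, summarizes and tests counts across grades, pools datasets, and
trains a small neural network that predicts the grade from the counts.
A synthetic-data module generates both planted-lesion masks (with XML
ground truth) and multi-dataset count cohorts, so every stage is
testable without clinical data.

## Instance counting

A binary mask tells us *where* lesions are, not *how many* there are.
The counter proceeds in two stages:

1. **Connected components** (`count_components()`): maximal connected
   foreground regions under 8-connectivity (diagonally touching pixels
   of a round lesion belong together; 4-connectivity is available).
   Components below `min_size = 3` px are discarded as annotation
   noise.  The paper trail for every labeled pixel is kept in a
   `labeled_mask`.
2. **Watershed splitting** (`split_touching()`): adjacent lesions merge
   into one component, so within each component we compute the exact
   Euclidean distance transform (EDT), place markers at its local
   maxima, and flood the component from the markers (priority flood on
   decreasing distance).  A component with one marker is left alone —
   an isolated lesion can never be over-split — and total foreground
   area is conserved exactly.

Three marker rules make the split robust on a pixel grid, and all three
are explicit, tunable parameters of `counting_params()`:

* **Plateau collapse.**  Discrete EDTs are full of ties; 8-connected
  plateaus of candidate maxima collapse to a single representative
  (highest value, then lowest scan index — fully deterministic).
* **`marker_min_distance` (default 5 px).**  Markers closer than this
  merge greedily, strongest first.  Two fused lesions are recognized as
  two only when their cores are at least this far apart.
* **`marker_min_prominence` (default 0.5 px).**  After flooding,
  regions whose marker rises less than this above the saddle joining
  them to a neighbour are merged back (the classic maxima-dynamics /
  h-maxima guard, computed exactly with a Kruskal pass over boundary
  saddles).  This removes spurious peaks that grid discretization
  creates along the ridge between two genuine lesion cores, at zero
  cost to peaks with real prominence.

HE area (`measure_he_area()`) is a trivial but clinically motivated
companion metric: hard exudates aggregate into clusters, so in severe
disease their count is less stable than the fraction of the image they
cover.

RL counts are the *sum* of the MA and Hma counts, not a count of the
union mask.  Summing matches the definition of red lesions as the two
classes considered jointly and avoids merging an MA that merely touches
an Hma; the union-mask alternative would systematically undercount.
Missing inputs propagate: a lesion class without a mask is *not
annotated*, never zero.

## Outlier filtering

Real-world datasets contain images whose annotations are unreliable —
grossly over-segmented, mislabeled, or inconsistent with the clinical
definition of their grade.  `filter_outliers()` applies the standard
interquartile-range rule: within each stratum, a record is excluded
when its MA **or** Hma count falls outside
[Q1 − 1.5·IQR, Q3 + 1.5·IQR].  HE values never trigger exclusion.

Choices worth knowing:

* **Stratification** defaults to dataset × grade.  Pooling grades would
  place the bounds across wildly different distributions and
  systematically delete legitimate severe cases (severe counts are
  *supposed* to be large).  `"dataset"` and `"global"` modes are
  available for sensitivity analysis.
* **Quantile convention** defaults to linear interpolation between
  closest ranks (R's type 7); `lower`/`higher` order-statistic variants
  are exposed.
* **Single pass.**  Bounds are computed once on the input table and
  applied once.  Re-filtering a filtered table would remove more rows
  (the bounds shrink); that is deliberately not done, and not
  idempotence-tested.
* Strata with fewer than 4 usable values get degenerate bounds and pass
  unfiltered, with a logged note.

The `FilterReport` records, per stratum and lesion, the quartiles,
bounds, sizes before/after, and the identity of every excluded record —
filtering is fully auditable, and the excluded set plus the retained
set partition the input exactly.

## Severity statistics

`stratum_summary()` reports mean counts with 95% confidence intervals;
`weighted_mean_across_datasets()` pools per-dataset summaries with
weights proportional to stratum sizes, which is algebraically the mean
of the pooled records; the pooled CI is computed from the exactly
reconstructed pooled variance (within- plus between-dataset sums of
squares).

* **CI form**: Student-t on the mean.  Counts are skewed, so the t
  interval is an approximation, but it is the symmetric mean ± CI form
  the field reports; a seeded percentile bootstrap (2000 resamples) is
  available via `ci_method = "bootstrap"`.
* **Group comparisons**: two-sided *unpaired* Wilcoxon rank-sum
  (Mann–Whitney) tests.  The severity groups are independent samples,
  which dictates the rank-sum form (a *signed-rank* test would require
  pairing).  The exact null distribution is used when both groups have
  ≤ 25 observations and no ties; otherwise the normal approximation
  with tie and continuity correction.  Two groups with all values
  identical (e.g. two all-zero strata) have no evidence of a shift and
  are reported as p = 1.  Labels: `***` < 0.001, `**` < 0.01,
  `*` < 0.05, `NS` otherwise.
* **No multiple-testing correction** is applied by default, matching
  the per-pair reporting convention; comparisons default to adjacent
  grades, with all pairs available.

## The classifier

`train_classifier()` fits a single-hidden-layer feed-forward network —
7 sigmoid hidden units, softmax output over the four grades,
cross-entropy loss with an L2 weight-decay penalty of 0.001 on all
weights, trained by BFGS — on z-scored features.  These defaults are
the canonical small count-feature classifier configuration; the
implementation is self-contained (about sixty parameters; `optim()`
with analytic gradients) because no neural-network package is assumed
at run time.

* **Split**: stratified 80/20 by class, seeded.  Stratification
  protects the small no-DR and severe classes from vanishing out of
  the training set.
* **Scaling hygiene**: centers and spreads are estimated on the
  training split only and stored with the model; test rows can never
  influence them.
* **Features**: MA, Hma and HE counts by default.  RL is excluded
  because it is an exact linear combination of MA and Hma; a flag
  restores it.
* **Report**: 4×4 confusion matrix (rows = truth), overall accuracy,
  and per-class sensitivity (diagonal over row sum; `NA` for absent
  classes).

## The synthetic world

The study datasets are not public, so the generator *is* the test bed.
It states a world and sticks to it:

* **Counts** are zero-inflated negative binomial per (grade, lesion),
  with target means equal to the published post-filter per-grade means:
  MA 4.3 / 14.2 / 53.1 (mild/moderate/severe), Hma 8.7 / 51.1,
  HE 30 / 58.2 (moderate/severe).
* **Dispersion** is chosen by lesion biology, not fitted: MA size 3
  (punctate, well segmented — the tightest), Hma size 1.5 (prone to
  confluence), HE size 0.6 with 20% zero inflation (cluster-forming —
  deliberately the widest, and visibly so in the pooled CIs).  The
  published CI widths themselves cannot be matched by any i.i.d.
  profile: they pool four heterogeneous datasets, so they carry a
  between-dataset variance component that a shared profile does not
  have.  Matching them would require absurd dispersions whose upper
  tails the IQR filter then amputates, biasing every mean far below its
  target.  This is a stated limitation: synthetic CIs at the study's
  sample sizes are narrower than the printed ones.
* **No-DR and mild are not exactly empty.**  Real-world graded no-DR
  images carry stray MA annotations — visible in the published no-DR
  classifier sensitivity of only 60% — so no-DR MA is NB(0.8, size 1).
  Mild red lesions exceed mild MAs in the published summaries (4.6 vs
  4.3), so no-DR and mild both carry an *identical* trace Hma profile
  (Poisson, mean 0.35): identical, so the no-DR vs mild Hma comparison
  stays non-significant, as reported; Poisson, so the per-stratum IQR
  bound (Q3 = 1) retains the trace counts instead of zeroing them.
* **Unreliable images** are planted at rate 0.11 (the published
  2445 → 2175 filtering shrink) by redrawing MA/Hma counts at 5–8× the
  stratum mean, in strata whose mean is at least 2 — a fivefold
  multiple of a near-zero mean is not a "heavy" count.  The planted
  identities are returned as filtering ground truth.
* **Masks** plant filled disks (MA 2–5 px radius, Hma 4–12, HE 5–15 —
  plausible relative scales; only the ratios matter) at random
  in-bounds centers, with an exact XML mapping of class and centroid.
  Planted overlaps are *resolvable by construction*: each lesion's
  distance-transform peak clears the valley joining the pair by at
  least 2 px (center distance ≥ √(r₁²−m²) + √(r₂²−m²) + 0.5 px with
  m = min(r) − 2), and centers are at least 8 px apart.  Pairs below
  that prominence are physically indistinguishable from a single blob
  at pixel resolution — that regime is confluence, a documented
  limitation of lesion segmentation, not a test of the splitter.
* **Cohort structure** mirrors the study: four datasets of 144, 586,
  1395 and 50 images; moderate-heavy grade mixtures; the smallest
  dataset restricted to moderate/severe.  The per-dataset grade
  mixtures are this package's own choice (the source reports only
  qualitative imbalance), fixed once.

What a green test does and does not establish: the pipeline recovers
the stated means, orderings and significance patterns from data *drawn
from those profiles*.  It does not validate lesion segmentation
(upstream, out of scope), does not reproduce the published 86.9%
accuracy (that number depends on the non-public merged dataset), and
does not model image-quality artifacts, vessels, or annotation-protocol
differences between graders.

## Numerical and degenerate-input choices

* Grayscale masks binarize at intensity > 127/255 (midpoint; masks are
  nominally binary, the threshold only guards against antialiased
  exports); RGB masks collapse by any-channel-nonzero.
* Coordinates are 0-based (row, col), origin top-left, in masks and
  XML alike.
* Labels, plateau representatives, marker order, flood order and tie
  breaks are all deterministic; the same seed reproduces every output
  byte-for-byte.
* Empty strata yield `NA` sentinels, never errors; `n = 1` strata yield
  degenerate CIs equal to the mean; fewer than 4 values disable the
  IQR filter for that stratum with a warning.
* p-values outside [0, 1] are rejected loudly; all-tied rank-sum inputs
  return p = 1 rather than dividing by a zero variance.

## Known limitations

* TIFF masks are not read (no TIFF decoder in the supported
  environment); PNG only.
* The IQR rule with zero-IQR strata annihilates any lesion whose
  within-stratum distribution has more than 75% zeros; this is a
  property of the method, not a bug, and is why trace profiles in the
  generator are Poisson rather than more zero-inflated shapes.
* The classifier's published accuracy is not a target: with count-only
  features and clean synthetic labels, held-out accuracy lands above
  0.9 — higher than the published 86.9% because the synthetic world
  lacks grader disagreement and image noise.  The orderings (moderate
  most sensitive, no-DR weakest) do reproduce.
* Confluent lesions below the prominence threshold are counted as one;
  the counting accuracy targets hold for ≤ 20% overlap rates.
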