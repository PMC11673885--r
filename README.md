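# drquant

Quantification of retinal microvascular lesions for diabetic
retinopathy (DR) severity grading.

DR severity is conventionally reported on the ICDR scale — no DR, mild,
moderate, severe non-proliferative DR — a coarse, qualitative grading.
Counting the individual lesions in a single macula-centered fundus
image gives the grade a numerical backbone: microaneurysm (MA) and
hemorrhage (Hma) counts rise steeply and consistently with grade, their
union (red lesions, RL = MA + Hma) likewise, and hard exudates (HE)
follow with wider dispersion.  `drquant` implements that analysis for
anyone holding per-lesion binary segmentation masks and ICDR grades —
reading masks and manifests, counting lesion instances, filtering
unreliable records, summarizing and testing counts across grades,
pooling heterogeneous datasets, and classifying severity from counts.

## What it computes

* **Instance counting** — connected-components analysis on the binary
  mask (8-connectivity, minimum size 3 px), refined by a
  marker-controlled watershed on the exact Euclidean distance transform
  that splits touching lesions: markers at distance maxima separated by
  ≥ 5 px, with shallow regions (maxima dynamics < 0.5 px) merged back.
  HE area is measured as foreground pixels and image fraction.
* **Outlier filtering** — the 1.5 × IQR rule on MA and Hma counts,
  stratified by dataset × grade, single pass, with a full audit report
  (bounds and excluded identities per stratum).
* **Severity statistics** — per-stratum means with 95% t-based CIs,
  two-sided unpaired Wilcoxon rank-sum tests between grades (exact for
  small tie-free groups), significance labels (`***` < 0.001,
  `**` < 0.01, `*` < 0.05, `NS`), and sample-size-weighted pooling
  across datasets with exact pooled variances.
* **Classification** — a single-hidden-layer network (7 sigmoid units,
  weight decay 0.001, softmax output, BFGS) on z-scored counts with a
  stratified, seeded 80/20 split; confusion matrix, accuracy and
  per-class sensitivity.
* **Synthetic data** — planted-disk masks with XML ground truth, and
  four-dataset count cohorts drawn from severity profiles calibrated to
  published per-grade means (MA 4.3/14.2/53.1, Hma 8.7/51.1,
  HE 30/58.2 for mild/moderate/severe), with an 11% planted
  unreliable-record rate.

## Worked example

Generate the default synthetic four-dataset cohort (2175 images),
filter it, pool it, test it, classify it:

```r
library(drquant)

gen <- generate_count_table(cohort = cohort_spec(seed = 7))
res <- filter_outliers(gen$table)
print(res$report)
#> <filter_report> 1.5 x IQR rule on MA/Hma, stratified by dataset_grade
#>   records: 2175 -> 1867 (14.2% excluded)

w <- weighted_summaries(summarize_strata(res$filtered))
w[w$lesion %in% c("MA", "RL"), ]
#>     grade lesion total_n pooled_mean ci_low ci_high
#>     no_DR     MA     158         0.5    0.4     0.6
#>     no_DR     RL     158         0.8    0.7     1.0
#>      mild     MA     423         4.3    4.0     4.6
#>      mild     RL     423         4.6    4.3     4.9
#>  moderate     MA     954        14.2   13.6    14.8
#>  moderate     RL     954        22.9   22.2    23.7
#>    severe     MA     332        53.8   50.8    56.8
#>    severe     RL     332       102.7   97.7   107.6

wilcoxon_pairwise(res$filtered, NULL, "MA", "moderate", "severe")
#> moderate vs severe MA: W = 19281, p = 5.86e-126, label ***

tr <- train_classifier(build_features(res$filtered),
                       classifier_config(seed = 7))
print(tr$report)
#>           predicted
#> truth      no_DR mild moderate severe
#>   no_DR       21   11        0      0
#>   mild         4   78        3      0
#>   moderate     0    2      184      5
#>   severe       0    0        9     57
#> accuracy: 0.909 on 374 held-out samples
#> per-class sensitivity:
#>    no_DR     mild moderate   severe
#>    0.656    0.918    0.963    0.864
```

Reading the numbers: pooled mean counts rise monotonically with grade
(mild ≈ 4 MAs per image, moderate ≈ 14, severe ≈ 53; red lesions reach
≈ 100 at severe), adjacent grades differ with p ≪ 0.001, and counts
alone classify the held-out 20% with ~0.91 accuracy — moderate NPDR is
the most recognizable class, while no-DR (scarce, and separated from
mild only by a handful of stray lesions) is the weakest.

On real data, point the pipeline at a manifest CSV
(`dataset_id,image_id,grade,ma_mask,hma_mask,he_mask`) referencing
per-class PNG masks:

```r
counts <- count_dataset(read_manifest("manifest.csv"))
```

or run everything from the command line (subcommands `simulate`,
`count`, `filter`, `stats`, `classify`, `run-all`; JSON config):

```sh
Rscript -e 'drquant::cli_main()' run-all --out results --seed 7
```

## Scope

Lesion segmentation (producing the masks), image-quality QC, IRMA
detection and proliferative DR are out of scope.  The methods vignette
(`vignettes/lesion-quantification.Rmd`) documents the model, the
synthetic-data calibration and its limitations in detail.
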