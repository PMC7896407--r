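# fdgsubtypes

Data-driven subtyping of Alzheimer's-disease-related neurodegeneration
from FDG-PET, as a tested and fully reproducible R pipeline.

Reduced FDG-PET signal (hypometabolism) is a sensitive marker of
neurodegeneration, and its regional pattern differs systematically
between patients: a *typical* posterior temporo-parietal pattern, a
*limbic-predominant* pattern centred on the medial temporal lobe, and a
rarer *cortical-predominant* pattern that spares the medial temporal
lobe. This package implements the full analysis that discovers such
subtypes and carries them forward to prognosis:

* **Discovery** — Ward agglomerative clustering of voxel-wise FDG-PET
  profiles scaled to their global mean (so clustering reflects the
  regional pattern, not overall severity). The merge cost is the
  within-cluster sum-of-squares increase
  ΔSSE(A,B) = n_A·n_B/(n_A+n_B)·‖c_A − c_B‖², updated via the
  Lance-Williams recurrence; the number of clusters is chosen by the
  silhouette criterion with Davies-Bouldin reported alongside.
* **Characterization** — voxel-wise two-sample t tests on pons-scaled
  images with age/gender/education covariates, converted to Cohen's
  d = t·√(1/n₁ + 1/n₂) effect-size maps; covariate-adjusted group
  comparisons with BH-corrected post hocs; A/T/N biomarker
  classification (AV45 SUVR ≥ 1.11; CSF Aβ < 880, p-tau > 19.2,
  t-tau > 242 pg/ml).
* **Prodromal classification** — a two-stage automated classifier: a
  screen flagging any of 48 cortical regions with pons-scaled signal at
  least 1 SD below the control mean (no flags → "no hypometabolism"),
  then nearest-centroid matching of globally scaled profiles to the
  dementia-derived subtype means.
* **Outcomes** — progression from CDR 0.5 to ≥ 1 analysed with
  Kaplan-Meier curves and Cox proportional hazards (Breslow ties), and
  domain-specific cognitive decline with linear mixed models (random
  intercepts and slopes, Satterthwaite inference).

Because the cohorts such analyses run on are access-controlled, the
package ships a first-class **synthetic cohort generator** that plants
the subtype structure (default mixtures 79/86/12 of 177 dementia and
57/108/49/3 of 217 prodromal subjects, hazard ratios 4.82/5.99 versus
no-hypometabolism), so every stage is validated by planted-truth
recovery. See the methods vignette
(`vignettes/fdg-subtyping-methods.Rmd`) for the generative model and all
modelling decisions.

## Worked example

```r
library(fdgsubtypes)

# discovery cohort: 179 CN + 177 AD-dementia subjects
disc <- simulate_cohort(cohort_config(seed = 42),
                        groups = c("CN", "AD"), longitudinal = FALSE)
fit <- fit_subtypes(disc, k_range = 2:10)   # smooth, scale, cluster, select k
fit
#> subtype_fit: k = 3
#>               subtype  n       pct
#>  cortical_predominant 12  6.779661
#>    limbic_predominant 79 44.632768
#>               typical 86 48.587571
```

The silhouette criterion selects three clusters, and the recovered
cluster sizes are 79/86/12 — i.e. 44.6% limbic-predominant, 48.6%
typical and 6.8% cortical-predominant of the 177 dementia subjects.

```r
# classify an independent prodromal cohort against the fitted model
prod <- simulate_cohort(cohort_config(seed = 43), groups = "MCI")
asg <- classify_cohort(prod$images, prod$atlas, fit$model)
subtype_frequencies(asg$subtype)
#>                subtype   n       pct
#> 1 cortical_predominant   2  0.921659
#> 2   limbic_predominant 109 50.230415
#> 3    no_hypometabolism  63 29.032258
#> 4              typical  43 19.815668
```

29% of the prodromal cohort shows no region below the 1-SD screen
threshold (the planted no-hypometabolism fraction is 26.3%; the screen
trades a capped retention against misses of mildly affected subjects),
half are limbic-predominant, and the cortical-predominant subtype is
rare — two subjects here.

```r
# progression to dementia: planted hazard ratios recovered at scale
cfg <- cohort_config(n_cn = 0, n_ad = 0, n_mci = 6000, seed = 44,
                     subtype_proportions_mci = c(no_hypometabolism = 1/3,
                       limbic_predominant = 1/3, typical = 1/3,
                       cortical_predominant = 0))
sim <- generate_cross_sectional(prod$atlas, prod$templates, cfg,
                                groups = "MCI", images = FALSE)
lng <- generate_longitudinal(sim$cohort, cfg)
cox_ph(lng$events, covariates = character(0))$hr
#>              subtype   hr   lo   hi         p
#> 1 limbic_predominant 4.59 3.97 5.29  2.65e-96
#> 2            typical 5.87 5.10 6.76 8.16e-134
```

The Cox model recovers the configured hazard ratios (4.82 and 5.99)
within sampling error: prodromal patients with a disease-like
hypometabolism pattern progress to dementia roughly five to six times
faster than those without regional hypometabolism.

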