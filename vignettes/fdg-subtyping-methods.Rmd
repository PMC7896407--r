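---
title: "Methods: data-driven FDG-PET hypometabolism subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven FDG-PET hypometabolism subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`fdgsubtypes` implements a complete, testable pipeline for data-driven
subtyping of Alzheimer's-disease-related neurodegeneration from FDG-PET:

1. **Simulation** of FDG-PET-like cohorts with planted regional
   hypometabolism subtypes (a cognitively normal reference group, a
   dementia group mixing three disease patterns, and a prodromal group
   that includes a no-hypometabolism fraction), together with baseline
   biomarkers and longitudinal outcomes;
2. **Discovery**: Ward agglomerative clustering of globally scaled voxel
   profiles, with the number of clusters selected by internal validity
   criteria (silhouette, Davies-Bouldin);
3. **Characterization**: covariate-adjusted voxel-wise contrasts on
   pons-scaled images, converted to Cohen's *d* effect-size maps;
4. **Classification** of an independent prodromal cohort: a regional
   hypometabolism screen followed by nearest-centroid matching;
5. **Outcomes**: progression to dementia (Kaplan-Meier, Cox proportional
   hazards) and domain-specific cognitive decline (linear mixed models
   with random intercepts and slopes).

Because real multi-centre PET cohorts are access-controlled, the
simulator is a first-class component: it generates data with exactly the
statistical structure each downstream stage assumes, so that every stage
can be validated by planted-truth recovery.

# The generative model

A subject's unsmoothed image is

$$x_{iv} = g_i\,(1+\eta_i)\,b_{r(v)}\,(1+\beta_{i,r(v)})\,
  \bigl(1 - \min(s_i\,\delta_{r(v)},\,c)\bigr) + \epsilon_{iv},$$

for grey matter voxels $v$ in region $r(v)$, and
$x_{iv} = g_i\,b_{pons} + \epsilon_{iv}$ in the pons reference region,
where

* $g_i \sim \exp(\mathcal N(0, \sigma_g^2))$ is a global uptake factor
  (default $\sigma_g = 0.15$) — a pure nuisance: global-mean scaling
  removes it exactly, which is why the clustering operates on globally
  scaled profiles;
* $\eta_i \sim \mathcal N(0, 0.06)$ is a subject-level grey-matter versus
  pons coupling term. It cancels exactly under global scaling but is the
  dominant shared component of *pons-scaled* regional values. Without such
  a shared component, a screen flagging any of 48 regions below 1 SD of
  the control mean would flag essentially every truly-normal subject
  ($0.84^{48} \approx 10^{-4}$ of subjects would survive); with it, the
  no-hypometabolism retention is about 0.6–0.7, which is what makes
  a 1-SD screen a meaningful instrument — mirroring real reference-region
  scaling, where between-subject variance is strongly spatially shared;
* $\beta$ is smooth regional biological variation: subject loadings
  (SD 0.01) on three fixed spatial gradients (anterior-posterior,
  left-right, inferior-superior), zero in the pons;
* $s_i$ is a severity multiplier, $\mathrm{Gamma}(k{=}12)$ with mean 1.0
  in dementia and 0.5 in the prodromal group, capped so that
  $s_i \delta \le 0.9$;
* $\delta$ is the subject's subtype template: fractional uptake reductions
  per region;
* $\epsilon_{iv} \sim \mathcal N(0, 0.05)$ is voxel noise (uptake units,
  relative to a base uptake of 1).

In the noise-free limit (all SDs zero, $s$ fixed) the equation is exactly
invertible, and the test suite recovers $\delta$ from generated images to
machine precision.

## Subtype templates

The three planted disease patterns follow the field's description of
hypometabolic subtypes: a **typical** pattern with deep posterior
temporo-parietal involvement and mild medial-temporal reduction; a
**limbic-predominant** pattern with strong medial-temporal reduction
extending to mid-temporal and frontal cortex; and a
**cortical-predominant** pattern with frontal/anterior involvement and a
spared medial temporal lobe. A flat no-hypometabolism template completes
the set.

Two design choices matter and were made once, during model design:

* **Template supports are largely disjoint** (each pattern occupies its
  own anterior-posterior tertile of the cortical screening areas plus its
  defining pattern regions). Overlapping designs that mimic the shared
  "AD-like" component of real patterns give centered-pattern correlations
  around $-0.6$; after global scaling all subjects then lie near one
  severity axis, and no internal validity criterion can see three
  clusters. With disjoint supports the centered patterns are close to
  orthogonal and the planted structure is recoverable at the rates the
  pipeline's validation demands.
* **Severity dispersion**: globally scaled profiles are approximately
  $1 - s_i\,(\delta - \bar\delta)$, i.e. subjects lie on rays from a
  common apex, stretched by $s_i$. With a severity coefficient of
  variation of 0.5 (gamma shape 4), within-subtype spread along each ray
  exceeds the between-ray separation: Ward splits the largest cluster by
  severity before isolating the small cortical-predominant cluster, and
  the silhouette criterion prefers two clusters. The default shape of 12
  (CV $\approx$ 0.29) keeps substantial severity heterogeneity — and
  overlapping dementia/prodromal severity distributions — while making
  the planted three-cluster structure recoverable. The shape is a config
  field; users wanting maximal heterogeneity can set
  `severity_shape = 4` and will see the stage-versus-subtype confound in
  action.

## What the simulator does *not* emulate

Realistic anatomy, partial-volume effects, scanner harmonization,
spatial normalization, and registration error are out of scope: all
volumes live in the voxel space of the synthetic template. Passing
planted-truth tests therefore demonstrates the correctness and the
statistical behaviour of the pipeline, not its robustness to
registration or scanner effects in real data.

# Preprocessing conventions

* **Smoothing**: separable Gaussian, $\sigma = FWHM/(2\sqrt{2\ln 2})$
  per axis, kernel truncated at $4\sigma$ and renormalized, zero-padded
  boundaries. The default 8 mm FWHM at 4 mm voxels matches standard PET
  practice. The truncation and padding conventions are fixed so smoothed
  fixtures are bit-reproducible.
* **Global-mean scaling** divides in-mask values by their mean
  (idempotent, homogeneous of degree zero) — used for clustering and
  nearest-centroid matching, making both invariant to global severity.
* **Pons scaling** divides by the mean pons signal — used for contrasts
  against controls and for the hypometabolism screen, where global
  scaling would mask disease-related global reductions.
* **Masking**: clustering profiles are restricted to the grey-matter
  mask. This excludes reference-region and background voxels from the
  distance metric; whether the original analyses used masked or
  whole-brain voxels is not documented, so the mask is a sensitivity
  switch (`gm_profiles` works on any mask the atlas defines).
* **Regional summaries** are unweighted voxel means.

# Clustering

Ward's criterion is implemented from first principles with the merge cost
stored as the increase in within-cluster sum of squares,
$\Delta SSE(A,B) = \frac{n_A n_B}{n_A+n_B}\lVert c_A - c_B\rVert^2$,
updated by the Lance-Williams recurrence. Two conventions are pinned:

* heights on the $\Delta SSE$ scale; `as.hclust(tree, "ward_d2")`
  converts to the $\sqrt{2\,\Delta SSE}$ scale used by
  `hclust(method = "ward.D2")` — a monotone map, so topology and cuts are
  identical (asserted against `hclust` in the tests);
* exact ties merge the pair with the smallest (min leaf id, max leaf id),
  making trees deterministic.

Reducibility of Ward's criterion guarantees non-decreasing merge costs;
this is asserted on every tree, as is the conservation law that the merge
costs sum to the total SSE about the grand centroid. An exhaustive
$\Delta SSE$-search oracle validates the greedy merges for small n.

The number of clusters is chosen by cutting the dendrogram at each
candidate k (default 2–10) and evaluating both the mean silhouette width
(maximized; Rousseeuw's conventions — singletons and zero-distance points
score 0) and the Davies-Bouldin index (minimized; coincident centroids
are a degeneracy error). When the criteria disagree the silhouette choice
is primary and the conflict is reported, never silently resolved —
matching how such disagreements are handled in practice. On toy data with
tight pairs, Davies-Bouldin can favour singleton splits ($S_i = 0$); this
is a property of the index and is covered by a test.

# Contrast maps

Voxel-wise two-group contrasts fit intensity on intercept + group +
covariates (age, gender 0/1, education in years, uncentered) by least
squares; the group t statistic is converted to Cohen's
$d = t\sqrt{1/n_1 + 1/n_2}$, the standard two-sample conversion (a
monotone alternative such as Hedges' g would change map values but not
rankings). Negative d means the
first group is lower — hypometabolism. No voxel-wise multiplicity
correction is applied because the maps are descriptive; `fdr_bh` is
available if thresholding is wanted. Adding a covariate orthogonal to the
design and the data leaves the coefficient untouched and rescales t only
through the residual degrees of freedom ($t' = t\sqrt{df'/df}$), which
the tests assert exactly.

# Prodromal classification

Two fully automated stages:

1. **Screen**: a subject passes when at least one cortical screening
   region has a pons-scaled regional mean at or below the control mean
   minus one control SD (the boundary is inclusive; boundary cases are
   measure-zero but the convention is fixed for exact tests). Subjects
   with no flagged region form the no-hypometabolism subtype. The control
   reference is computed from all CN subjects of the discovery sample.
2. **Matching**: screen passers are assigned to the dementia-derived
   subtype with the smallest Euclidean distance between the globally
   scaled profile and the subtype centroid, over all in-mask voxels.
   Exact ties go to the first subtype in the model's fixed order and are
   reported.

Two properties deserve emphasis. First, the screen's no-hypometabolism
retention is mathematically capped: even with perfectly correlated
regional deviations, a truly-normal subject survives 48 one-SD tests only
if its shared deviation exceeds $-1$ SD, which happens for ~84% of
subjects; residual regional variance pushes retention to ~0.6–0.7. The
planted 26.3% no-hypometabolism fraction therefore yields an *assigned*
fraction in the low-to-mid twenties, with screen misses of mildly
affected disease subjects compensating upward. Second, because the
retention cap bounds the no-hypometabolism recall below 0.85, balanced
accuracy of the classifier is assessed over the three disease subtypes
(the nearest-centroid stage), with the cortical-predominant cell excluded
when fewer than five subjects are planted — the default prodromal mixture
plants only three, too few to estimate a recall.

# Baseline and longitudinal outcomes

* **Composites**: the memory-executive discrepancy is MEM − EF (positive
  = relatively worse executive function). The hippocampal-to-cortical
  volume ratio is $1000\,HV/CTV$ per subject, averaged per subject before
  group summaries (ratio-of-means does not reproduce conventional
  reported values; the 1000 factor matches their magnitude).
* **A/T/N**: amyloid positivity at AV45 SUVR $\ge 1.11$ (CSF
  A$\beta < 880$ pg/ml only when SUVR is missing, strict), tau at p-tau
  $> 19.2$ pg/ml (strict), neurodegeneration at t-tau $> 242$ pg/ml
  (strict); missing inputs give "unknown".
* **Group tests**: ANOVA/ANCOVA F test on the group factor, with
  pairwise covariate-adjusted t tests only when the global test passes
  $p < 0.05$, BH-adjusted; chi-square (no continuity correction) with
  pairwise 2×2 comparisons for compositions. Missingness is handled by
  listwise deletion with counts reported.
* **Progression**: the event is the first visit with CDR $\ge 1$ after a
  0.5 baseline; non-progressors are censored at their last visit. Cox
  models use Breslow tie handling by default (Efron behind a flag) with
  the no-hypometabolism subtype as reference; non-convergence (e.g.
  complete separation) raises a diagnostic error rather than returning
  implausible estimates. Note the generator also exposes the latent
  continuous event times: parameter-recovery checks use those, because
  interval-censoring onto a 6-month visit grid plus Breslow ties biases
  hazard ratios toward the null by a few percent — a property of the
  estimator, not a bug.
* **Trajectories**: `score ~ month * subtype + age + gender + education`
  with per-subject random intercepts and slopes; Satterthwaite degrees of
  freedom via `lmerTest`, falling back to a normal approximation when the
  approximation fails, and to ordinary least squares for degenerate
  (zero-variance) data, with the path recorded in the result. In balanced
  complete data the interaction estimate equals the difference in group
  means of per-subject OLS slopes, which the tests assert to $10^{-6}$.

# Problem sizes and numerical choices

The default synthetic study uses an 18×22×18 grid at 4 mm voxels
(~2,700 grey-matter voxels, 48 cortical screening regions of ≥ 8 voxels
each), 179 CN / 177 dementia / 217 prodromal subjects, 6-monthly visits
with per-subject follow-up of 12–72 months (mean ≈ 42), and a baseline
hazard of 0.003/month giving roughly 35% progression events under the
default hazard ratios (4.82 and 5.99 versus no-hypometabolism; the
cortical-predominant ratio has no published counterpart and defaults to
the typical value). Validation suites run 100 simulation seeds for
cluster-number recovery and classification, and 1,000–12,000 subjects for
survival parameter recovery — sizes at which the Monte-Carlo error is
comfortably below the asserted tolerances. Ward trees use exact
arithmetic with a $10^{-12}$ relative band for tie detection; cluster
renumbering is by decreasing size with ties by smallest member id.

# Known limitations

* The atlas and images are geometric idealizations; no claim is made
  about performance under registration error or scanner effects.
* Template depths, longitudinal slopes and random-effect scales are
  package defaults chosen to be realistic, not quantities calibrated to
  any dataset; within-subtype pattern heterogeneity in particular is a
  free parameter.
* The screen's behaviour is sensitive to the control sample's estimated
  regional SDs (a single shared component dominates all 48 regions), so
  the no-hypometabolism fraction varies by a few percentage points with
  the discovery cohort — visible in the acceptance outputs across seeds.
* Davies-Bouldin and silhouette can legitimately disagree; the package
  reports both and never resolves the conflict silently.
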