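---
title: "Tract lesion burden and EMR anxiety phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tract lesion burden and EMR anxiety phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractburden)
```

This vignette documents the scientific model behind `tractburden`, the
choices made where the design was genuinely open, and what the synthetic
cohorts do and do not demonstrate about real data.

## The problem

Anxiety affects a large fraction of people with multiple sclerosis, and
whether white-matter lesion topography contributes to it is an open
question. The package operationalizes one testable version of that
question: *do lesions that disrupt the uncinate fasciculus (UF), the tract
connecting orbitofrontal cortex and amygdala, carry more weight for anxiety
than lesions elsewhere?* Answering it at clinical scale requires three
ingredients that this package implements as separable modules: a phenotype
derivable from routine EMR data, a per-patient per-tract injury score, and
a covariate-adjusted association model with specificity controls.

## EMR anxiety phenotyping

Anxiety is systematically under-coded in medical records, so presence of a
single marker is treated as informative while absence is not. The rules
are:

- **severe**: an anxiety diagnosis (ICD-10 prefix F40/F41) **and** an
  anxiolytic order — symptom burden high enough to be both coded and
  treated;
- **mild**: exactly one of the two;
- **none**: no F-chapter diagnosis, no psychiatric medication, and at
  least one PHQ-2 or PHQ-9 observation, all with score 0. A quiet record
  without a confirmatory PHQ is **excluded** rather than assumed healthy,
  as is a quiet record with any nonzero PHQ.

Two consequences are worth stating. First, the four labels partition all
records — this is property-tested over randomized records. Second, the
no-anxiety group has mean PHQ-2 of exactly 0 *by construction*; the
pipeline reports it as a sanity check, not as a finding.

Decimal points in codes are ignored during prefix matching ("F41.1"
matches "F41"). The anxiety block defaults to F40 *and* F41 because F41
(generalized anxiety, panic) is the dominant billing code for anxiety; the
prefix lists and both medication dictionaries are configuration
(`codeDictionaries()`, YAML-loadable), not code. Which drugs count as
anxiolytics is a site-formulary question — the shipped list contains
GABAergic agents, buspirone and hydroxyzine, deliberately excluding
SSRIs/SNRIs, which instead appear in the antidepressant list of the binary
depression comparator (F32/F33 or an antidepressant). No time window links
PHQ observations to the MRI date; the phenotype is a lifetime construct.

PROMIS scoring selects, per domain, the observation closest in time to the
patient's first MRI (ties broken toward the earlier observation), then
averages 4 physical-functioning domains and 6 emotional/social domains.
Missing domains are skipped and counted; a summary with zero contributing
domains is returned as `NA` with a flag rather than silently dropped.

## The burden metric

A streamline is **injured** when any of its resampled points falls in a
lesion voxel. Volumes are voxel-counting volumes of the *union* of voxels
traversed by a set of streamlines, so heavily overlapping streamlines are
not double-counted, and

$$\mathrm{burden} \;=\;
\frac{(V^{inj}_L + V^{inj}_R)/2}{(V^{can}_L + V^{can}_R)/2}.$$

Because the injured voxel set is always a subset of the canonical set,
burden provably lies in [0, 1], and adding lesion voxels can never
decrease it; both properties are tested, the latter over random mask
growth chains.

Numerical conventions, fixed for bit-reproducibility:

- Polylines are resampled so consecutive samples are at most half the
  smallest voxel edge apart — on a straight segment at 1 mm spacing no
  voxel can be skipped. Refinement stability (halving the step changes
  nothing on straight segments) is tested.
- A point belongs to the voxel whose centre is nearest after applying the
  inverse grid affine; exact half-way ties round away from zero. Voxel
  centres sit at integer (0-based) indices, the NIfTI convention.
- Sampled-vertex membership (not segment-voxel clipping) defines
  traversal. This convention is common in tractography tooling but not
  universal; it is part of the metric's definition here.
- Masks must already live in the bundle's template space. An affine
  utility is provided; nonlinear registration is explicitly out of scope.

On grids up to 32³ the voxelization and injury calls are verified against
a brute-force oracle that scans every (sample point, voxel) pair.

## Statistical layer

The two hypothesis-driven models are Gaussian GAMs fitted by REML
(`mgcv`):

```
burden ~ phenotype + sex + total_brain_volume + s(age, bs = "cr", k = 4)
```

*Anxiety diagnosis* contrasts severe vs none (mild rows dropped); *anxiety
severity* enters as a single ordinal 0/1/2 slope — a "parametric"
three-group comparison. A factor-coded severity alternative exists behind
`predictor = "severity_factor"`. The reported T and p are the Wald
statistics of the parametric term. Both hypothesis-driven models use
unadjusted two-sided α = .05; FDR (Benjamini–Hochberg, Q < 0.05) applies
within the sensitivity family (fornix × 2, UF~depression, total lesion
volume × 3) and within the PROMIS t-test family.

Effect sizes: Cohen's f² = (R²_full − R²_reduced)/(1 − R²_full), where the
reduced model drops only the phenotype term and keeps all covariates; R²
is computed from residuals about the outcome mean. The CI is a percentile
bootstrap over patients (B = 1000 by default; the bundled demo uses
B = 100–200 to stay fast) with a documented seed. On the OLS special case
f² equals t²/df_resid, which the tests assert. Cohen's d uses the pooled
n − 1 SD; the paired contrasts use mean(diff)/sd(diff).

The age spline uses a penalized cubic regression basis with k = 4 —
enough to bend once or twice over an adult age range without inviting
wiggle — selected by REML. Requesting `splineK <= 2` collapses the smooth
to a linear age term (a cubic basis needs k ≥ 3), which is also how the
OLS-equivalence test pins the GAM machinery to `lm()` at 1e-6.

## The synthetic cohort generator

The generator emulates the study conditions the analysis assumes, with
defaults chosen once: 372 patients split 27/67/6% into none/mild/severe;
PHQ-2 group means ≈ 0, 0.57, 1.16 (capped Poisson on 0–6); age ≈ N(47.7,
11.4²) truncated to 18–85; 80% female; total brain volume ≈ N(1.2 × 10⁶,
1.1 × 10⁵²) mm³; UF burden targets (0.02, 0.05, 0.10) by group with
patient noise SD 0.04 truncated to [0, 1]; fornix target 0.05 for every
group; background (off-tract) lesion volume rising with group (1000, 2500,
4000 mm³) so total lesion volume tracks general psychopathology; PROMIS
emotional T-scores dropping 6 points per severity step against 2.4 for
physical, around a patient-level random intercept (SD 5, domain noise SD
8); 10% of latent no-anxiety patients lack a PHQ record and are therefore
excluded by phenotyping; 75% of mild/severe patients carry a comorbid
depression marker.

Toy tracts are jittered parametric arcs: mirror-symmetric UF analogs in an
inferior band and fornix analogs in a superior band, guaranteed disjoint
after voxelization so the control tract cannot pick up planted UF signal
by construction. Jitter draws are clamped at ±2 SD to keep every point
strictly inside the grid box; grids below 16 mm extent are rejected.

Lesion planting ranks tract voxels by the number of streamlines traversing
them — fewest first, with a deterministic id tie-break — and adds voxels
greedily until the recomputed burden reaches the target. Ranking ascending
makes the increments fine-grained (one low-coverage voxel injures one
streamline at a time), so mid-range targets are reachable to voxel
granularity; the planter raises an error naming the achievable step size
when a target cannot be met within ±0.05. The recomputed burden of every
planted mask equals the achieved value exactly, which is what makes the
planted-effect recovery tests sharp.

`makeCohort(imaging = FALSE)` skips the voxel grids and draws the burden
variables directly from the same truncated-normal target distributions.
This fast path exists for Monte-Carlo work — the power and type-I
calibration fit hundreds of GAMs — and is justified by the tested facts
that (a) phenotyping recovers latent groups exactly when no PHQ is
missing, and (b) planted imaging burdens match their targets to within the
planting tolerance. The imaging path is exercised end-to-end at smaller
cohort sizes (problem sizes used in the suite: 150 patients on a 48³ grid
for the acceptance cohort, 45–60 for pipeline tests, 400-patient tabular
cohorts × 100 seeds for power and 200 × 500 seeds for the null
calibration).

What the generator does **not** emulate: realistic lesion morphology
(planted voxels follow tract geometry, background voxels are scattered),
anatomically faithful tract shapes, registration error, scanner or site
effects, longitudinal change, and any coupling between lesion burden and
the PROMIS/PHQ observation process. Passing tests therefore demonstrate
that the pipeline's rules, metric and models do what they claim under
controlled conditions — not that the clinical effect exists; that question
belongs to real cohorts.

## Degenerate inputs and edge cases

- Burden is undefined (error) when both canonical volumes are zero;
  one empty hemisphere contributes 0 volume while the denominator still
  averages over two sides.
- A bundle wholly outside the grid is an error naming the tract; a
  frame-mismatch check (fraction of points inside the mask's world box)
  catches mask/bundle space confusion before silent zeros can.
- Records with malformed ICD codes fail loudly, listing the offenders.
- `cohensD` refuses zero pooled SD; `cohensF2` refuses R² = 1; the
  bootstrap skips resamples that lose the predictor contrast.
- All randomness flows from explicit seeds (one per generator call, one
  per pipeline run feeding named substreams), and reruns are
  byte-identical up to timestamps.

## Known limitations

Streamline volume uses sampled vertices rather than exact segment-voxel
intersection; with the half-edge resampling step the difference is
confined to voxels a segment clips through a corner. The burden metric
averages hemispheres even when one side is absent, which follows the
metric's definition but halves the contribution of unilateral tracts. The
EMR rules are only as good as the dictionaries supplied, and the shipped
medication lists are defaults, not a validated formulary mapping. The GAM
layer assumes Gaussian outcomes; burden near its floor of 0 is
heteroscedastic, which the type-I calibration shows is tolerable at the
simulated noise levels but is not a general guarantee.
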