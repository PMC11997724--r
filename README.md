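# tractburden

Anxiety is common in multiple sclerosis (MS), and one candidate mechanism is
demyelinating injury to the white-matter circuit connecting the orbitofrontal
cortex and the amygdala — the uncinate fasciculus (UF). `tractburden` is an R
package for testing that kind of hypothesis at EMR scale. It provides, as one
reproducible pipeline:

- **EMR anxiety phenotyping** — rule-based stratification of patients into
  *MS without anxiety*, *mild anxiety* (an F40/F41 diagnosis **or** an
  anxiolytic order) and *severe anxiety* (both), with psychiatrically quiet
  patients admitted to the no-anxiety group only when a PHQ-2/PHQ-9 score of
  0 confirms the absence of symptoms. A binary depression comparator uses
  the analogous rules.
- **Streamline-filtering lesion burden** — given a binary lesion mask and an
  atlas tract in a shared template space, streamlines intersecting any
  lesion voxel are isolated as *injured*, and

  ```
  burden = ((V_inj_L + V_inj_R)/2) / ((V_can_L + V_can_R)/2)
  ```

  where each `V` is the volume of the union of voxels traversed by the
  injured (resp. all) streamlines of that hemisphere. Burden is
  dimensionless in [0, 1].
- **PROMIS summary scoring** — physical (4-domain mean) and emotional
  (6-domain mean) functioning scores using the observation most proximal to
  the patient's first MRI.
- **Statistics** — generalized additive models
  `burden ~ phenotype + sex + total brain volume + s(age)` (penalized cubic
  spline, REML, via mgcv) with Wald T and p for the phenotype term, Cohen's
  f² = (R²_full − R²_reduced)/(1 − R²_full) with percentile-bootstrap CIs,
  Cohen's d, an ANOVA/χ²/Shapiro–Wilk/t-test battery and Benjamini–Hochberg
  FDR control, plus a sensitivity suite (fornix control tract, depression
  comparator, total lesion volume).
- **A synthetic cohort generator** — toy bilateral UF/fornix arc bundles,
  lesion masks greedily planted to hit per-group burden targets to voxel
  granularity, and EMR extracts engineered so the phenotyping rules recover
  the latent groups. Everything is testable without patient data.

File formats: NIfTI-1 masks (via RNifti), TrackVis `.trk` and MRtrix `.tck`
streamlines (interoperable with nibabel), long-format EMR CSV, YAML
configuration.

## Worked example

```r
library(tractburden)

cfg <- runConfig(outDir = "demo_out",
                 synth = list(nPatients = 120, seed = 1,
                              gridShape = c(48, 48, 48)),
                 bootstrapB = 50, seed = 7)
res <- runAll(cfg)
```

The run logs each stage and leaves `report.txt` in `demo_out/`; with the
seeds above it prints:

```
Hypothesis-driven models (alpha = .05, unadjusted):
  anxiety_diagnosis (uf_diagnosis) T = 3.97, P = 0.000382; Cohen f2, 0.49 [95% CI, 0.07-1.99] (n = 37)
  anxiety_severity (uf_severity) T = 5.19, P = 9.85e-07; Cohen f2, 0.25 [95% CI, 0.08-0.54] (n = 117)

Sensitivity analyses (BH-FDR within family):
  fornix_burden        ~ anxiety_severity     T = 1.88, P(FDR) = 0.0631
  total_lesion_volume  ~ anxiety_severity     T = 24.37, P(FDR) = 8.13e-46 *
  ...
```

Read: on this synthetic cohort the planted UF effect is recovered (positive
T, p < .05 for both the severe-vs-none contrast and the three-group severity
slope), the fornix — whose lesion overlap was planted independent of group —
stays null, and total lesion volume, which the generator couples to general
psychopathology, is significant in every model. `demo_out/report.json`
carries the same numbers machine-readably, and `manifest.json` records the
seed and config hash for reproducibility.

Individual stages are available as plain functions (`makeCohort`,
`classifyAnxiety`, `filterInjured`, `tractBurden`, `fitBurdenGAM`, ...), and
`inst/scripts/tractburden-cli.R` exposes them as shell verbs.

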