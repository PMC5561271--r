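---
title: "Methods: seed-based rsFC change analysis with Monte-Carlo cluster inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-based rsFC change analysis with Monte-Carlo cluster inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`seedfc` implements a pre-/post-task amygdala seed-based resting-state
functional connectivity (rsFC) analysis for multi-site cohorts, together
with a synthetic cohort generator that reproduces the statistical structure
such an analysis assumes. The pipeline is:

1. **Seed maps.** A bilateral seed is built as two 5 mm-radius spheres
   around stereotaxic (&plusmn;22, &minus;6, &minus;14) mm on a 3 mm
   isotropic grid; the two sphere means are averaged into one seed time
   course. Each subject-session's 180-volume (TR 2 s) run is correlated
   voxelwise with the seed course (Pearson), and r is mapped to Fisher z =
   atanh(r). For white series, z is approximately Normal(atanh(&rho;),
   1/(T&minus;3)); the package's null-calibration tests check exactly this.
2. **Site residualization.** Per voxel, z is regressed on site indicator
   dummies across all subject-sessions jointly and replaced by residual +
   grand mean, so each site's mean map is identical afterwards while the
   overall scale stays interpretable.
3. **Second level.** Within-group paired t maps (post vs pre), a
   between-group pooled-variance t map at baseline, and the group-by-time
   interaction F of the two-way mixed ANOVA. For a two-level within factor
   the interaction is *exactly* the one-way between-group ANOVA on change
   scores d = z_post &minus; z_pre, which is how the map is computed; the
   test suite proves the identity voxelwise against a brute-force
   `aov(y ~ group*time + Error(subject))` oracle.
4. **Cluster-extent FWE.** Maps are thresholded at voxel p = 0.01 (t maps
   two-tailed, F maps upper-tailed), clusters are labelled under
   26-connectivity, and the family-wise error across space is controlled at
   0.05 by a Monte-Carlo null of the maximum cluster extent (1000
   iterations at full scale): Gaussian fields at the estimated map
   smoothness, thresholded like the data map, labelled like the data map.
5. **Conjunction and restriction.** A common post-task network is a
   minimum-statistic conjunction of the two groups' paired t maps (same
   sign, both suprathreshold). Interaction clusters are only interpreted
   when they overlap (&ge; 1 voxel) the suprathreshold set of at least one
   group's paired t map; unsupported clusters are dropped with a logged
   reason.
6. **Correlates.** Per-subject cluster-mean z values feed simple-effects
   t tests and a medication post-hoc ANOVA; clinical scores (BPDSI, BSI,
   checklist, ITEC sum, dissociation change) are correlated with masked
   change maps, r maps are converted to t via t = r&radic;(n&minus;2) /
   &radic;(1&minus;r&sup2;) and corrected like t maps, and cluster-by-scale
   correlate families use a Bonferroni gate.

# The synthetic cohort generator

Real patient recordings for this design are not publicly available, so the
generator *is* the study-condition model: 2 sessions &times; 3 groups
(48/39/21 subjects) &times; 3 sites, 180 timepoints at TR 2 s, 3 mm
voxels. Per subject-session, a latent seed signal s(t) is AR(1) Gaussian
with unit marginal sd; seed-sphere voxels carry s plus independent noise;
a voxel of a network with coupling w carries w&middot;s +
&radic;(1&minus;w&sup2;)&middot;&epsilon; with &epsilon; an independent
AR(1) series — so every voxel's marginal variance is noise_sd&sup2;
regardless of w, a contract the suite tests. Remaining brain voxels carry
pure noise; a one-voxel border of near-empty background surrounds the
brain box so intensity-based masking has something to do.

Choices the data sources do not pin down, decided once:

* **AR(1) temporal structure** (default coefficient 0.3) is the minimal
  autocorrelation model that makes the Fisher-z variance 1/(T&minus;3)
  approximate rather than exact; calibration tests that assert exact
  normality set the coefficient to 0.
* **Per-subject coupling heterogeneity** (`coupling_sd`, default 0.15 on
  the atanh scale, split evenly between a stable subject effect and a
  session-specific deviation). Without it all subjects in a group would
  share one true change score and clinical scores could not correlate with
  connectivity change; 0.15 puts the between-subject sd of a true change
  score at 0.15 (the two session components have sd 0.15/&radic;2 each),
  comfortably above its measurement sd for a 40-voxel network at T = 180.
* **Site effects** act twice: an intensity gain/offset per site (what a
  scanner difference does to raw signal, invisible to correlations) and an
  additive per-site shift of network coupling on the atanh scale
  (`site_z_shift_sd`, default 0.05) — the component site residualization
  exists to remove.
* **Seed-voxel noise** (`seed_noise_sd` 0.2 relative to the latent signal)
  attenuates the extracted seed course only negligibly after averaging ~38
  sphere voxels (correlation with the latent &ge; 0.999).
* **Clinical links.** A linked score is intercept + slope &times; (true
  atanh-coupling change of the target network) + noise; `target_r` solves
  the noise sd for a requested population correlation via
  noise_sd = slope &middot; sd(&Delta;&zeta;) &middot;
  &radic;(1/r&sup2; &minus; 1). Unlinked scores are drawn from group-wise
  normal profiles (truncated at zero) matching a severe
  borderline-personality cohort, a non-patient group and a cluster-C
  group. The ITEC total is the unweighted sum of its five subscales.
* **Medication flags** are random within the first group at proportion
  31/48, purely to exercise the post-hoc ANOVA.

What the generator does *not* emulate: hemodynamic convolution, motion and
physiological artifacts, field inhomogeneities, spatially varying
smoothness, non-Gaussian noise. Passing recovery tests therefore shows the
statistical machinery is correct and calibrated under the assumed model,
not that the pipeline is robust to real-data artifacts.

# Numerical choices

* **Voxel indexing** is 1-based at the R surface (matching
  `RNifti::worldToVoxel`); affines keep the NIfTI 0-based convention, and
  all reports print mm coordinates. The mm&rarr;voxel tie-break is
  round-half-away-from-zero per axis.
* **Correlation clipping**: |r| is clipped at 1 &minus; 10&supminus;&#8311;
  before atanh, so self-correlated voxels give a large finite z.
  Zero-variance voxels give z = 0 with a warning rather than NaN.
* **Smoothness** is estimated from second-level change-score residual maps
  by the gradient-variance estimator FWHM_a = &Delta;_a &middot;
  &radic;(&minus;2 ln 2 / ln(1 &minus; v_a/(2v))), averaged over maps and
  floored at the voxel size (with a warning) when the log is undefined —
  the white-noise limit of the floored estimator is the voxel size.
* **Monte-Carlo null fields** are simulated on the mask's bounding box
  padded by twice the FWHM, smoothed, and restandardized within the mask
  *only when smoothing was applied*: restandardization exists to undo the
  variance shrinkage of smoothing, and applying it to an already-standard
  unsmoothed draw distorts exceedance probabilities on small masks.
* **Tail matching.** The extent null thresholds its Gaussian fields the
  way the data map was thresholded: two sign sets of density p/2 for
  two-tailed t maps (never merged), one set of density p for upper-tailed
  F maps (`tail = "upper"`). A split null under an unsplit map
  underestimates the critical extent — with the mismatched null the
  pipeline's family-wise error on null cohorts measured ~0.11 instead of
  0.05, which is why `apply_extent` refuses tables and nulls with
  different tails.
* **Cluster tables** order clusters by descending size, ties by peak value
  then lexicographic peak index, so outputs are deterministic. Cluster
  volumes are reported in voxel-native mm&sup3; (multiples of 27 mm&sup3;
  on the 3 mm grid); published tables produced by interpolating packages
  can print sizes that are not such multiples.
* **Pooled-variance t tests** (not Welch) match the classical ANOVA
  framework of the second level.
* The 2&times;2 chi-square uses no continuity correction: the printed
  crosstab statistics this package reproduces are Pearson statistics.

# Problem sizes in the test suite

The acceptance tests run the full pipeline at reduced sizes chosen once:
null calibration uses 200 cohorts of 2 &times; 10 subjects on a 16&sup3;
grid with 500-iteration nulls; interaction recovery uses 50 cohorts of
2 &times; 20 subjects on a 14 &times; 14 &times; 12 grid with a planted
40-voxel network (coupling 0.1 &rarr; 0.5 in one group); clinical-correlate
recovery uses 50 single-group cohorts of n = 48. All use T = 180
timepoints, the full-scale run length. `scripts/acceptance.R` repeats the
same measurements at 100/20/20 replicates.

# Known limitations

* The restriction and conjunction rules are voxel-overlap heuristics; they
  control interpretation, not error rates.
* The Bonferroni family for correlate tests is defined as clusters &times;
  scales; other family definitions are defensible and change the gate.
* The gradient-variance smoothness estimator assumes stationary Gaussian
  autocorrelation; its voxel-size floor makes the extent null mildly
  conservative for data smoother than white but rougher than one voxel.
* Education-level and MANOVA statistics of the descriptive table are out
  of scope (inconsistent printed counts / insufficient printed detail).
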