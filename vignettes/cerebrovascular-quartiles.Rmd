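---
title: "Quartile-based cerebrovascular quantification: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartile-based cerebrovascular quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasoquant)
```

## The problem

Cerebral blood volume (CBV) and the structure of the vascular network that
carries it can be measured with two complementary modalities. Ultrafast
power Doppler images a coronal plane in vivo at high frame rate; after
tissue clutter is removed, the per-pixel signal power is proportional to
the local blood volume. Confocal microscopy of lectin-stained (IB4)
post-mortem sections resolves the vessels themselves in 3D, so their
volume can be measured directly. In both modalities the measurement is
summarized the same way: the distribution is split into four groups,
Q1 through Q4, ordered from the largest vessels (large arteries and
veins) down to capillaries and venules, and group summaries are compared
between two genotypes — a wild type and a mutant modeling a hereditary
peripheral neuropathy with central correlates.

`vasoquant` implements both quantification chains, the gated statistics
used to compare them, and a synthetic-data module that generates all
three kinds of input with known ground truth, so that every stage of the
analysis can be verified by parameter recovery rather than by eye.

## Power-Doppler chain

An acquisition is a complex frame ensemble $s(z, x, t)$,
$t = 1 \dots N$ with $N = 350$ frames per image by default. The chain
is:

1. **SVD clutter filter.** The ensemble is reshaped into its
   space $\times$ time Casorati matrix $S$ and decomposed as
   $S = U \Sigma V^{*}$. Tissue motion is slow and of much higher
   amplitude than blood, so it concentrates in the first singular
   components; `svd_clutter_filter()` zeroes the `low` largest (and
   optionally `high` smallest) components and reconstructs. With cutoff
   $(0,0)$ the filter is the identity and conserves energy exactly;
   removing components can only decrease energy.
2. **Power image.** $P(z,x) = \frac{1}{N}\sum_t |s_f(z,x,t)|^2$, the
   temporal mean squared modulus of the filtered signal, proportional to
   CBV.
3. **dB referencing.** $P_{dB} = 10\log_{10}(P/P_{ref})$. For *display*
   the reference is conventionally the maximum inside the structure of
   interest (e.g. the hippocampus), so its brightest pixel is 0 dB. For
   *quantitative group comparison* the package references the maximum of
   the whole analyzed section instead. The reason is arithmetic: if a
   genotype effect scales a region's CBV uniformly and the reference is
   taken inside that same region, the scaling cancels in the ratio and
   the effect is invisible in dB. Referencing outside the affected
   region (the package places the brightest simulated vessels in the
   cortex band, as superficial pial vessels are in vivo) preserves it.
   Both conventions are available in `to_db()`.
4. **Intensity quartiles.** ROI pixels are sorted by decreasing dB and
   split into four equal-count groups: Q1 is the brightest quarter
   (largest vessels), Q4 the dimmest. Remainder pixels go to the
   earliest quartiles and boundary ties are broken by raster-scan order,
   so the partition is deterministic and its counts differ by at most
   one pixel. The ROI pixel count is stored as the normalization
   constant, which makes per-quartile means comparable across animals
   with different section sizes. An equal-dB-width variant is exposed
   (`method = "range"`) but is not the default: equal-count quartiles
   are the standard distribution quartiles and remain defined when the
   dB histogram is heavy-tailed.

### Cutoff selection

The clutter cutoff is chosen for the best signal recovery. With ground
truth available (simulations), `select_cutoff()` scores candidates by
the correlation between post-filter power and the true CBV map; since
the score plateaus once the clutter subspace is removed, the smallest
cutoff within a small tolerance of the best score is returned rather
than the argmax — removing further components only discards blood
signal. Without truth, a singular-value elbow heuristic picks the
candidate at the largest drop of the log spectrum. Both are stand-ins
for the operator's signal-to-noise judgement; the heuristic is
documented as such.

## Confocal chain

A section is a 3D fluorescence stack with voxel size in micrometers.
Two consecutive slices are concatenated axially
(`merge_consecutive_slices()`) to form a thickness comparable to the
Doppler plane. The chain is Otsu binarization (the between-class
variance maximizer on a 256-bin histogram of the full stack — the
default automatic threshold of the common image-analysis tools),
3D connected-component labeling (26-connectivity by default,
6 selectable), and then:

* **Vessel volume fraction.**
  $VVF = 100 \times \frac{\text{vessel volume}}{\text{total section volume}}$,
  computed on voxel counts. A fully vascularized section is exactly
  100%.
* **Volume quartiles.** Objects are sorted by decreasing volume and
  assigned greedily: each object joins the current quartile until its
  cumulative volume first reaches 25% of total vessel volume, then
  assignment advances; Q4 takes the remainder. With discrete objects an
  exact 25/25/25/25 split is impossible in general; the greedy
  first-crossing rule guarantees non-empty leading quartiles and bounds
  each quartile's deviation from 25% by one object's volume, and with
  many equal-volume objects it is exact. Alternatives (midpoint
  crossing, volume splitting) would fragment objects or leave leading
  quartiles empty; the choice is deliberate and the per-quartile shares
  are always reported so the deviation is visible.
* **Normalized vessel count.** Objects per mm³ of section, the
  size-independent count summary.

Conservation holds by construction: per-quartile VVFs sum to the total
VVF exactly, because the assignment is a partition.

## Gated statistics

Every comparison first passes each sample through a Shapiro–Wilk
normality gate at $\alpha_{norm} = 0.05$ (the package's choice; the
convention is common but rarely stated). Two-group comparisons then use
the classical equal-variance Student's t test when both groups pass and
the Mann–Whitney U test otherwise; a Welch variant is selectable.
Within-genotype quartile blocks (the same animals measured in Q1–Q4) use
a repeated-measures one-way ANOVA with subject as blocking factor and
Bonferroni-adjusted paired t tests post hoc when all four columns pass
the gate, and the Friedman test with Bonferroni-adjusted paired Wilcoxon
signed-rank tests otherwise. Because the block design is ambiguous in
the source protocols ("one-way ANOVA" over repeated measurements), a
plain one-way variant is available behind `repeated = FALSE`. All tests
are two-sided. No correction is applied across endpoints — only the
within-block pairwise comparisons are Bonferroni-adjusted
($p_{adj} = \min(1, 6p)$) — matching the analysis convention the package
reproduces; this is documented rather than silently "improved".

Constant vectors make the Shapiro–Wilk statistic undefined; the gate
declares them non-normal and sets a degenerate flag, so downstream
routing stays deterministic.

The gate-then-test compound procedure is calibrated by simulation in the
test suite: its type-I error at $\alpha = 0.05$ stays within
$[0.03, 0.07]$ for both normal and skewed nulls (1000 replicates each),
so gating does not distort the nominal level at the study's sample
sizes.

## What the synthetic data emulates — and what it does not

**Vascular networks** are straight tubular segments (with occasional
single branches) in four caliber classes. The caliber taxonomy fixes
only the ordering; no published diameter ranges exist for the four
classes, so the package defaults are radius bands of 15–30, 8–15, 4–8,
and 1.5–4 µm chosen to give four well-separated volume scales, and they
are config-overridable. Segment counts default to roughly
$1/r^2$-proportional values so each class contributes a comparable total
volume. A voxel is foreground iff its center lies within the segment
radius of a centerline; this rasterization is checked exactly against a
brute-force per-voxel distance evaluation. The networks are *not*
physiologic trees — no bifurcation hierarchy, tortuosity, or
anatomically realistic hippocampus geometry — which is sufficient for
volumetry and quartile logic but means passing tests say nothing about,
e.g., centerline extraction on real data.

**Confocal rendering** is mask → Gaussian PSF blur → contrast and
background → additive Gaussian noise clipped at zero. Defaults:
`psf_sigma` 1 µm (subvoxel at 2 µm sampling, as a confocal PSF is),
`noise_sd` 5 against a contrast of 100 over background 10. With zero
blur and noise, thresholding recovers the truth mask exactly; at the
default noise the full pipeline recovers VVF to well within 15%
relative error. Real stain heterogeneity, depth attenuation, and
mosaicking seams are not modeled.

**Doppler ensembles** are the sum of (i) low-rank clutter: smooth
complex spatial modes times orthonormal low-frequency cosine temporal
modes, scaled to a configurable multiple of the blood RMS (default 30×,
up to 100× in stress tests), (ii) blood signal: frame-to-frame
independent circular complex Gaussian with per-pixel power proportional
to the CBV map (fast decorrelation is the limiting case of ultrafast
acquisition; no velocity spectrum is modeled), and (iii) complex white
noise (default 0.1× blood RMS). Rank separation is the property the
filter needs, and it is what the simulator guarantees; beamforming,
angle compounding, speckle, and motion are out of scope.

**Behavioral tables** draw count endpoints from a negative binomial
(dispersion 5 — overdispersion is typical of behavioral counts) and
duration endpoints from a gamma. Default genotype shifts point in the
directions of an anxious-like, motor-impaired mutant phenotype (fewer
entries and rearings, more freezing, grooming, defecation and head
shakes, shorter rotarod permanence); a `zero_shift` switch produces null
tables for calibration.

## Study conditions and problem sizes

The simulated cohorts mirror the study design the package emulates: 12
animals per genotype for Doppler and behavior, 4 per genotype for
confocal, 350 frames per Doppler plane, a +30% hippocampal CBV effect
and no cortical effect in the mutant group, and a 15% vessel-radius
(dilation) effect for the confocal hippocampus. Between-animal
variability is a lognormal regional gain with 10% coefficient of
variation, a realistic scale for regional perfusion differences.

Simulated image sizes are deliberately compact so that full
power-and-calibration experiments (hundreds of cohorts, thousands of
gate-then-test replicates) run on a single CPU: Doppler planes are
24×24 pixels, network volumes 64×128×128 voxels at 2 µm, and confocal
cohort tiles 12×120×120 voxels at 6×2×2 µm (two merged 6-plane slabs,
i.e. two consecutive 36 µm sections). The statistics are computed per
pixel, per object, and per animal, so none of the quantitative claims
depend on the plane or tile being large; the sizes are stated here as
the package's chosen conditions.

## Numerical choices

* Quartile boundary ties: raster-scan order (deterministic); remainder
  pixels to the earliest quartiles.
* Greedy volume partition: cumulative thresholds carry a relative
  epsilon (1e-9) so exact 25% crossings on equal objects are not missed
  to floating-point accumulation.
* Otsu histogram: 256 bins over the observed range; constant stacks are
  rejected (no separable classes) rather than thresholded arbitrarily.
* dB of zero power is `-Inf` and is left as such; it can only occur in
  noise-free synthetic input.
* All generators restore the caller's RNG state and derive per-stage
  seeds from one root seed through named substreams, so pipeline stages
  can be re-run independently and runs are bit-reproducible.

## Known limitations

* The intensity-quartile definition (equal pixel count) and the greedy
  volume partition are documented choices among several defensible
  readings of "quartiles"; both alternatives that were rejected are
  available or described above.
* The elbow cutoff heuristic is a stand-in for operator SNR judgement
  and is only validated on simulated spectra.
* Synthetic vessels can touch and merge into one connected component at
  realistic densities, exactly as stained vessels do; the volume
  quartile partition then concentrates volume in Q1. This is a property
  of connected-component volumetry itself, not of the implementation.
* No registration between Doppler and confocal coordinates is attempted;
  the two modalities are compared at the level of quartile summaries,
  not pixels.
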