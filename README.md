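# vasoquant

Quartile-based quantification of the cerebral vascular network from two
imaging modalities, with the gated statistics needed to compare genotypes
— plus a ground-truthed synthetic-data module so every stage can be
verified by parameter recovery.

**Who it is for.** Groups quantifying cerebral blood volume (CBV) with
ultrafast power Doppler and vascular structure with confocal microscopy
of lectin-stained brain sections, who want the whole analysis —
clutter filtering, quartile segmentation, 3D volumetry, statistics —
as reproducible, tested code instead of ad-hoc scripts.

## The methods in brief

**Power Doppler.** A complex frame ensemble `s(z, x, t)` (350 frames per
image by default) is reshaped to its space × time Casorati matrix and
clutter-filtered by SVD: the largest singular components carry slow,
high-amplitude tissue motion and are zeroed. The power image
`P = mean_t |s_f|²` is proportional to CBV; it is expressed in decibels
against a reference `P_dB = 10 log10(P / P_ref)` (the maximum of a
reference ROI), and ROI pixels are split into equal-count intensity
quartiles Q1 (brightest quarter — largest vessels) through Q4
(capillary-scale signal), with the ROI pixel count stored as the
normalization constant.

**Confocal volumetry.** 3D stacks of two consecutive sections are merged
axially, binarized with the automatic (between-class-variance / Otsu)
threshold, and labeled into 3D connected components (26-connectivity).
The vessel volume fraction is

```
VVF = 100 × vessel volume / total section volume   (%)
```

and objects are partitioned into volume quartiles: sorted by decreasing
volume and assigned greedily so each quartile's cumulative volume first
reaches 25% of the total vessel volume — Q1 large arteries and veins,
Q2 smaller arteries and veins, Q3 arterioles/venules, Q4
capillaries/venules. A normalized vessel count (objects per mm³) is also
reported.

**Statistics.** Every comparison is gated by a Shapiro–Wilk normality
test: two-group comparisons use Student's t when both groups pass and
Mann–Whitney U otherwise; within-genotype quartile blocks use
repeated-measures one-way ANOVA with Bonferroni post hoc when all
columns pass and the Friedman test otherwise.

**Synthetic data.** Tubular vascular networks in four caliber classes
(rasterized with an exact distance-to-centerline rule), confocal
renders (PSF blur + background + noise), Doppler ensembles (low-rank
clutter + fast-decorrelating flow signal with power ∝ CBV + white
noise), and behavioral score tables for two genotypes — all with known
ground truth and bit-reproducible under a fixed seed.

## Worked example

```r
library(vasoquant)

## --- power Doppler: simulate, filter, quantify -----------------------
cbv   <- matrix(seq(0.1, 0.8, length.out = 400), 20, 20)  # true CBV map
truth <- doppler_truth(cbv, clutter_rank = 2, clutter_amplitude = 30)
ens   <- simulate_doppler_ensemble(truth, seed = 1)
filt  <- svd_clutter_filter(ens, svd_cutoff(low = 2))
pd    <- to_db(power_doppler(filt,
               roi_masks = list(section = matrix(TRUE, 20, 20))), "section")
intensity_quartiles(pd, "section")
#> <quartile_summary> roi = section, n = 400 pixels (count)
#>  quartile    mean_db n_pixels boundary_db
#>        Q1 -0.7983652      100   -1.346090
#>        Q2 -1.9940941      100   -2.612552
#>        Q3 -3.7194360      100   -4.852786
#>        Q4 -6.6077304      100   -9.376597
```

The quartile means step down from Q1 (containing the 0 dB reference
pixel) to Q4; each quartile holds exactly a quarter of the 400 ROI
pixels, and the mean dB per quartile is the quantity compared across
animals.

```r
## --- confocal: render, binarize, label, VVF --------------------------
net     <- generate_vessel_network(seed = 1)     # ground-truthed network
stack   <- render_confocal(net, seed = 2)        # synthetic IB4-like stack
objects <- label_components_3d(binarize(stack))
100 * net$n_vessel_voxels / prod(net$volume_shape)  # truth
#> [1] 6.442928
compute_vvf(objects)                                # recovered
#> [1] 6.443119
volume_quartile_partition(objects)
#> <vvf_result> total VVF = 6.443%
#>  quartile vvf_percent volume_share n_objects
#>        Q1   4.0147781    62.311097         1
#>        Q2   0.6516457    10.113823         1
#>        Q3   0.5293846     8.216279         1
#>        Q4   1.2473106    19.358802        33
```

The estimated VVF matches the ground-truth voxel fraction to four
significant digits at the default noise level. Here the largest vessels
touch and fuse into one connected component, so Q1's share exceeds 25%
— the greedy partition reports the deviation instead of hiding it
(its bound is one object's volume).

```r
## --- gated statistics ------------------------------------------------
compare_groups(rnorm(12, 10), rnorm(12, 12))
#> <group_comparison> student_t: statistic = -6.058, p = 4.257e-06, effect (b - a) = 2.269
```

An end-to-end synthetic study (behavior + Doppler cohort + confocal
cohort + comparison report, all written to disk) is one call:

```r
report <- run_pipeline(default_run_config(seed = 1, out_dir = "run1"))
```

or from a shell, via the thin CLI in `inst/cli/vasoquant.R`:

```sh
Rscript inst/cli/vasoquant.R run --seed 1 --out run1
```

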