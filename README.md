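# hybridose

Patient-specific internal dosimetry for Tc-99m labelled
radiopharmaceuticals (somatostatin-receptor imaging of neuroendocrine
tumours being the motivating application), built around the **hybrid
planar/SPECT technique**: a series of whole-body planar scans supplies each
organ's washout kinetics, a single quantitative SPECT/CT supplies absolute
organ activity, and the two combine into time-integrated activity
coefficients (TIACs) that drive both voxel-level and organ-level
absorbed-dose calculations.

The package is aimed at medical-physics researchers who want a fully
inspectable, reproducible implementation of this chain — including a
synthetic digital-phantom simulator so every stage can be validated against
known ground truth without any patient data.

## The model in brief

For each source region $r$, the time-integrated activity coefficient is

$$\tilde a_r = \frac{1}{A_{\mathrm{inj}}}\int_0^\infty A_r(t)\,dt \quad [\mathrm{h}],$$

estimated by fitting a mono-exponential $A_0\,2^{-t/T_{\mathrm{eff}}}$ to
background-corrected planar ROI counts (ROI at 50% of the regional
maximum, propagated across the scan series by rigid registration) and
rescaling with the absolute SPECT activity at one time point:

$$\tilde a = \frac{A_{\mathrm{SPECT}}\,2^{\,t_{\mathrm{SPECT}}/T_{\mathrm{eff}}}}{A_{\mathrm{inj}}}\cdot\frac{T_{\mathrm{eff}}}{\ln 2}.$$

SPECT volumes are reconstructed with OSEM (2 iterations, 10 subsets,
matched attenuated projector), converted to Bq via a point-source camera
calibration, and segmented by **dual iterative adaptive thresholding**: two
calibration curves $T(\mathrm{SBR}) = a + b/\mathrm{SBR}$, built from
sphere-phantom reconstructions, give the thresholds recovering true volume
and true activity as a function of the observed signal-to-background
ratio.

Doses come from two arms sharing one physics core:

- **voxel level** — convolution of the cumulated-activity map with an
  analytic Tc-99m voxel S-value kernel (local electron deposition plus a
  photon point kernel with energy-conserving linear buildup), decomposed
  into self- and cross-organ dose, with cumulative DVHs;
- **organ level (MIRD)** — $D_t = \sum_s \tilde a_s\,S(t\leftarrow s)$ with
  S-factors derived from the same phantom and kernel, mass adaptation
  ($m^{-1}$ electron, $m^{-2/3}$ photon self terms), a dynamic
  voiding-bladder model, and a spherical self-dose model for tumours.

## Worked example

A complete simulated study of a ~25 kg child on a 48-voxel grid: three
planar scans (1.5, 5, 22 h), SPECT/CT at 4 h, Poisson noise, known
generator kinetics. Takes about a minute (most of it building the
segmentation calibration curves, which are cached).

```r
library(hybridose)
cfg    <- demo_study_config(seed = 1, poisson = TRUE)
report <- run_study(cfg)

report$tiacs[, c("region", "tiac_h", "truth_h")]
#>            region     tiac_h truth_h
#> 1     left_kidney 0.18824865 0.18500
#> 2    right_kidney 0.18468754 0.18500
#> 3           liver 0.56719639 0.56000
#> 4          spleen 0.41768449 0.43000
#> 5         tumor_1 0.06809967 0.07000
#> 6      whole_body 7.46873970 5.41101
#> 7 urinary_bladder 0.71328156      NA
#> 8       remainder 5.32954140 3.98101

report$doses[, c("region", "voxel_mGy_per_MBq", "cross_pct",
                 "organ_adapted_mGy_per_MBq")]
#>         region voxel_mGy_per_MBq cross_pct organ_adapted_mGy_per_MBq
#> 1  left_kidney        0.06093611 14.266194                0.06005680
#> 2        liver        0.03064739 19.912201                0.03033893
#> 3 right_kidney        0.06056168 13.617545                0.05970597
#> 4       spleen        0.13297404  5.677777                0.13129459
#> 5      tumor_1        0.07987134 14.043415                0.07909052
```

Reading this: measured organ TIACs (hours, per unit injected activity)
land within a few percent of the generator truth; the whole-body and
remainder rows are biased high by the single-exponential whole-body
assumption (discussed in the methods vignette). `voxel_mGy_per_MBq` is the
mean organ dose per MBq injected from kernel convolution; `cross_pct` is
the share of that dose contributed by activity *outside* the organ — the
component an isolated-organ model misses; the last column is the
organ-level MIRD result with measured masses, which tracks the voxel arm
closely. `report$dvhs` holds the cumulative dose-volume histograms and
`write_study_report(report, dir)` exports everything as deterministic CSV.

Larger phantoms reproduce cohort-level dose structure, e.g.

```r
organ_cross_fractions(pediatric_phantom_spec(grid_n = 96),
                      c(left_kidney = 0.185, right_kidney = 0.185,
                        liver = 0.56, spleen = 0.43, remainder = 5.01))
```

computes per-organ self/cross decompositions for a 12-year-old-scale torso
populated with literature mean TIACs.

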