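---
title: "Hybrid planar/SPECT dosimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid planar/SPECT dosimetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hybridose` implements the complete quantitative chain of a hybrid
planar/SPECT internal-dosimetry study for Tc-99m labelled
radiopharmaceuticals (the setting it was written for is somatostatin-receptor
imaging of neuroendocrine tumours, where the organs at risk are the kidneys,
liver and spleen). This vignette is the package's account of the science: the
models, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations.

## The dosimetry model

The quantity of interest for every source region $r$ is the time-integrated
activity coefficient (TIAC, historically the "residence time"),

$$\tilde a_r \;=\; \frac{1}{A_{\mathrm{inj}}}\int_0^\infty A_r(t)\,dt
\qquad [\mathrm{h}],$$

which the hybrid technique estimates from two complementary measurements:

* a series of 2-3 whole-body **planar** scans between roughly 1.5 and 24 h
  post-injection, which fixes the *shape* of each organ's washout: a
  mono-exponential $A(t) = A_0\,2^{-t/T_{\mathrm{eff}}}$ fitted to
  background-corrected ROI counts, giving the effective half-life
  $T_{\mathrm{eff}}$ and, through
  $1/T_{\mathrm{bio}} = 1/T_{\mathrm{eff}} - 1/T_{\mathrm{phys}}$, the
  biological half-life (negative when the organ still accumulates tracer at
  the end of the observation window, as spleens commonly do);
* one quantitative **SPECT/CT**, which fixes the *absolute scale*: the organ
  activity $A(t_{\mathrm{SPECT}})$ from OSEM reconstruction, camera
  calibration, and adaptive-threshold segmentation.

Combining the two under an instantaneous-uptake assumption,

$$\tilde a \;=\;
 \frac{A_{\mathrm{SPECT}}\;2^{\,t_{\mathrm{SPECT}}/T_{\mathrm{eff}}}}
      {A_{\mathrm{inj}}}\;\frac{T_{\mathrm{eff}}}{\ln 2}.$$

Instantaneous uptake is justified by the measured uptake phase of this
tracer class: kidney uptake peaks within 7-10 min
(the generator's biexponential uptake option reproduces this:
$t^{*} = T_{\mathrm{up}}\log_2(1 + T_{\mathrm{eff}}/T_{\mathrm{up}})$),
which is negligible against multi-hour washout sampled from 1.5 h onwards.

Doses are computed two ways and compared:

* **voxel level**: the dose map is the convolution of the cumulated-activity
  map (MBq h per voxel) with a voxel S-value kernel; per-organ means are
  split into *self* dose (from the organ's own activity) and *cross* dose
  (everything else), and cumulative dose-volume histograms are reported;
* **organ level** (MIRD schema):
  $D_t = \sum_s \tilde a_s\, S(t \leftarrow s)$ with S-factors *derived from
  the same phantom and kernel*, optionally mass-adapted, plus a spherical
  self-dose-only model for tumours.

Because the organ-level S-factors are derived from the voxel kernel rather
than copied from external phantom tables, the agreement of the two arms for
uniform intra-organ activity is a structural property (they share every
ingredient), and the package asserts it as a hard 2% test. Comparisons
against reference-phantom software would instead inherit that software's
anatomy.

## The synthetic-data generator

No patient data ship with the package; every analysis is exercised on a
digital phantom whose ground truth is known.

**Geometry.** An elliptical-cylinder torso (26 x 18 cm at the pediatric
reference) with ellipsoidal organs: paired kidneys (~210 g), liver
(~1050 g), spleen (~105 g), an optional 30 mL spherical tumour and optional
bladder. A single `age_scale` multiplies all linear dimensions: 1.0
approximates a 12-year-old (40 kg), 1.2 gives adult-like organ masses
(kidneys ~360 g, liver ~1830 g, spleen ~180 g, 73 kg), 0.8 a ~25 kg child.
These are reference-anatomy magnitudes, not a fit to any patient. The
default tumour sits in the anterior mid-abdomen, separated from kidneys and
liver by more than one PSF width; tumours may be placed anywhere, but
objects closer than the system resolution to a hotter neighbour will
inherit its spill-over, exactly as in clinical images.

**Kinetics.** Mono-exponential washout per organ with effective half-lives
of 4.72/4.94 h (kidneys), 5.07 h (liver), 5.83 h (spleen), 4.18 h (tumour),
amplitudes chosen so the organ TIACs are ~0.19/0.19/0.56/0.43/0.07 h -- the
magnitudes reported for this tracer class. Half of the injected activity is
excreted renally with a 2 h biological half-life. The whole-body activity is
physical decay times urinary retention; the remainder region carries
whatever the explicit organs do not. Since the imaged volume is a torso, the
remainder concentration is whole-body remainder activity divided by total
body mass: only the torso's mass fraction of the remainder activity lands in
the grid (`torso_mass_fraction()`), and the same bookkeeping is applied
wherever printed whole-body remainder TIACs populate a phantom (both
dosimetry arms).

**Acquisition.** Parallel-beam projection with exponential attenuation
(water-equivalent mu at 140 keV, scaled by tissue density), a
distance-*independent* Gaussian PSF (default FWHM 10 mm), sensitivity
90 cps/MBq per head, and Poisson counting noise under a mandatory seed
(fixed seed implies bit-identical data). SPECT uses 60 projections of 20 s
over a circular 360-degree orbit on a square matrix at 4.418 mm pixels;
planar sweeps default to 1.5/5/22 h with a free effective duration of 180 s
(whole-body scan speed is protocol-dependent, so it is a parameter, not a
constant). The projector is built from per-angle sparse bilinear rotation
operators, so its transpose is the exact adjoint -- the matched
projector/backprojector pair that both the simulator and OSEM use.

What the generator does **not** emulate: anthropomorphic anatomy, scatter
photon transport (the reconstruction's broad-beam rescaling exists for real
data; simulated data are scatter-free, so matched closure runs use
`broad_beam_scale = 1`), non-circular orbits, distance-dependent collimator
response, dead time, and patient motion (ROI registration is exercised with
rigid shifts). Passing closure tests therefore demonstrates the
*self-consistency* of the chain under its own assumptions, not performance
on clinical data.

## Reconstruction and quantification

OSEM with 2 iterations and 10 subsets (interleaved view selection),
multiplicative updates with the attenuated, PSF-matched projector, and a
Gaussian post-filter (default FWHM 8 mm) standing in for the vendor Hann
filter, whose cutoff is rarely reported; filter type and width are
configuration. The forward model carries a $1/n_{\mathrm{views}}$ factor so
that reconstructed voxel counts divide by
$\mathrm{sensitivity}\times$ total orbit time (1200 s) to give activity --
the calibration contract that ties `osem_reconstruct()`,
`counts_to_activity()` and `calibrate()` together. Camera sensitivity comes
from a point-source acquisition in air (default 4.82 MBq vial, 300 s),
averaging the two heads.

## Segmentation: dual iterative adaptive thresholds

Two calibration curves $T(\mathrm{SBR}) = a + b/\mathrm{SBR}$ (percent of
the regional maximum) are fitted on sphere-in-warm-background phantoms
pushed through the same simulate-reconstruct pipeline: one threshold
recovers the true volume, the other the true activity. At segmentation
time, the observed SBR (mask maximum over the mean of a 2-voxel background
shell at a 2-voxel gap around the seed box) selects the thresholds, and
thresholding iterates until the volume changes by <1% (20 iterations cap,
oscillation detection, inclusive `>=` tie handling).

Numerical choices worth knowing:

* the activity curve is calibrated against the object's *excess* activity
  over background (what a background-subtracted sum can actually recover);
  reported total activity restores the background concentration over the
  measured volume;
* the background shell is restricted to tissue (a support mask) -- shell
  voxels in air would inflate the SBR -- and can exclude neighbouring hot
  organs together with a 3-voxel spill halo, as an operator would;
* the default calibration grid is volumes {12, 30, 100} mL at SBR
  {2, 8, 32}, noiseless, on a 48-voxel grid whose background cylinder is
  sized relative to the sphere so the shell always sees clean background;
* at 4.418 mm voxels a 12-20 mL object spans only 60-90 voxels, and the
  achievable mask volumes are quantised in shells; volume errors of tens of
  percent for the smallest objects are a resolution floor, while the
  calibrated *activity* estimate remains accurate to a few percent. This is
  why the method's validity bound is stated as >= 12 mL and why tests
  assert volume closure at sizes the grid can actually resolve.

## TIAC engine

Whole-body TIAC uses the same mono-exponential machinery on total planar
counts with the $t=0$ fraction fixed to 1 (by definition of whole body).
When a large fraction of the activity is excreted early (the default
generator excretes half with $T_u = 2$ h), the whole-body curve is a
two-component decay and the late-time mono-exponential fit overestimates
its integral; the subtraction-based remainder inherits that bias. This is a
property of the method itself, not of the implementation, and it is why
closure tolerances are asserted for organs rather than for the remainder.

The urinary-bladder TIAC comes from a dynamic voiding model: inflow
$f_u \lambda_u e^{-\lambda_u t}$ (decayed physically once in the bladder),
complete voiding at fixed intervals, trapezoidal integration over ten
physical half-lives at a 0.005 h step (checked against the closed form in
the no-voiding limit). The defaults $f_u = 0.5$, $T_u = 2$ h, voiding
interval 3.5 h are declared assumptions -- organ-level codes name this
model without publishing parameters -- and are configurable.

## The voxel S-value kernel

Electron and low-energy conversion/Auger emissions (~16 keV per decay in
total) deposit in the source voxel. Photons follow an analytic point
kernel per emission line,

$$\Phi(r) = \frac{y\,E\,(\mu_{\mathrm{en}}/\rho)\,B(\mu r)\,e^{-\mu r}}
{4\pi r^2},$$

with linear buildup $B(\mu r) = 1 + a\,\mu r$. The coefficients
($\mu/\rho$, $\mu_{\mathrm{en}}/\rho$, $a$; water) and the Tc-99m emission
table are packaged data, log-log interpolated in energy. The buildup
coefficient is fixed by energy conservation, $a = \mu/\mu_{\mathrm{en}} - 1$
per line, so that the kernel integrates to unit absorbed fraction in an
unbounded medium. This matters: with small ad-hoc buildup the kernel
absorbs only a third of the emitted photon energy and the dose from distant
sources -- precisely the cross-organ component -- is underestimated
severalfold. A linear buildup redistributes multiply-scattered energy only
approximately in radius, which is the main physics approximation relative
to a Monte Carlo kernel; an independent radial-quadrature oracle bounds the
grid kernel's absorbed energy to within a few percent, and the acceptance
suite holds it to 10%.

The self-voxel photon term averages the point kernel over the equal-volume
sphere (a finite, slightly conservative value for the singular
$1/r^2$ centre). The kernel grid defaults to the acquisition voxel
(4.418 mm) with a configurable half-extent; dose maps use zero-padded FFT
convolution (negative residues clipped after a $10^{-12}$ tolerance check)
and are verified against an $O(N^2)$ brute-force double sum to $10^{-9}$.

## Organ-level arm

S-factors are the mean dose over each target per unit cumulated activity
uniformly in each source, computed with the voxel kernel on the phantom
itself; the electron component is kept separate from the photon component.
Mass adaptation scales the self terms by $(m_{\mathrm{ref}}/m)$ for
electrons and $(m_{\mathrm{ref}}/m)^{2/3}$ for photons -- the standard
absorbed-fraction scalings -- and leaves cross terms untouched. The
remainder S-factor column carries the same torso-mass-fraction bookkeeping
as the voxel arm. Tumour doses use the spherical model: electron self-dose
$\Delta_e \tilde a/m$ plus the photon point kernel averaged over the
sphere's pair-distance distribution
$p(s) = \frac{3s^2}{R^3}\left(1 - \frac{3s}{4R} + \frac{s^3}{16R^3}\right)$;
cross dose is excluded by construction, which is why sphere-model tumour
doses undershoot voxel-level doses for tumours near hot organs.

Patient age enters continuously through `age_scale` rather than by
quantising to the nearest of a few reference-phantom ages; nothing in the
mass-adaptation algebra requires discrete models, and the continuous route
avoids a spurious step dependence of dose on age.

## Problem sizes and reproducibility

The test suite runs the full pipeline on a 48-voxel demonstration grid (a
0.8-scale child), where one simulated study takes a few seconds; the
cross-organ dose studies use the full 96 (pediatric) and 128 (adult) grids
at 4.418 mm with a kernel half-extent of half the grid. Stochastic
properties are asserted over 50 seeded pipeline runs and 200 seeded fit
recoveries. Every stochastic component takes an explicit seed; a fixed seed
reproduces simulated data, reports and CSV outputs byte for byte (report
writers emit no timestamps for this reason).

## Known limitations

* Homogeneous water medium for dose (density enters masses and attenuation,
  not kernel transport); no heterogeneity correction.
* Linear energy-conserving buildup instead of Monte Carlo photon transport;
  accurate in total energy, approximate in its radial distribution.
* No scatter simulation, hence no test of the broad-beam compensation
  against true scatter; `broad_beam_scale = 0.75` is the clinical default,
  1.0 the matched-simulation value.
* Distance-independent PSF and circular orbit; quantification is
  orbit-agnostic but resolution modelling is not attempted.
* Planar kinetics assume organs resolvable in projection; overlapping
  structures (e.g. a kidney behind the liver) are out of scope, as is
  deformable registration.
* Whole-body/remainder TIACs inherit the single-exponential whole-body
  assumption (see above).
* Objects near 12 mL at 4.418 mm voxels are at the volume-quantisation
  floor; their activity, not their volume, is the reliable output.
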