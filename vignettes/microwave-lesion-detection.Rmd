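---
title: "Microwave breast-image analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave breast-image analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwibreast)
```

## The problem

Microwave breast imaging exploits the dielectric contrast between healthy
and lesioned tissue.  A multi-bistatic device records the complex
transmission parameter S21 between a fixed-radius transmitting antenna and
a receiving antenna stepped around the breast; a linear, qualitative
*intensity map* of the coronal plane is reconstructed from these signals.
`mwibreast` implements the downstream analysis chain for such maps —
reconstruction, adaptive segmentation, and a non-parametric
malignant-vs-rest classifier — together with a synthetic data generator, so
the whole chain can be exercised and tested without access to clinical
recordings (which are not publicly deposited).

## Acquisition model

The geometry follows the clinical device: 80 receiving positions every
4.5° on a ring of radius $a_0 = 7$ cm, ten transmitting positions arranged
as two-member *doublets* in five sections centered at 0°, 72°, 144°, 216°
and 288° on a 30 cm ring, and a 1–9 GHz sweep.  The device samples every
5 MHz (1601 frequencies); analyses in this package default to a decimated
sweep (typically every 500 MHz, 17 frequencies) because the incoherent
frequency sum converges quickly and the runtime budget of a test suite is
better spent elsewhere.  The angular separation of the two doublet members
is not published; we default to 9° (two adjacent slots) and expose it as
`doublet_offset`.

The forward simulator is a deliberately minimal single-scattering (Born)
model: each inclusion contributes
$a \, G(k_0 |r_{tx} - r_{inc}|) \, G(k_0 |r_{inc} - r_{rx}|)$, on top of a
direct-coupling term evaluated from the *section center* so that it is
exactly common to both doublet members.  It is a test bed for the imaging
operator, not a physics claim: no multiple scattering, mutual coupling,
antenna patterns or cup rim.

## Image formation

For each section the two doublet recordings are subtracted, removing every
transmitter-independent contribution (direct coupling, static artifacts)
exactly.  The internal field is synthesized by propagating the differenced
signals from the receiver ring into the domain with a cylindrical-wave
kernel,

$$E(\rho, \phi; m; f) \propto \sum_{n=1}^{80} \Delta S21(n, m, f)\,
  G\!\left(k_1 |\vec\rho_n - \vec\rho\,|\right),$$

and the map is the incoherent sum $I(\rho,\phi) = \sum_m \sum_i
|E(\rho,\phi;m;f_i)|^2$ over sections and frequencies, evaluated on a
polar grid (1 mm radial, 3° azimuthal, 7 cm radius) and bilinearly
interpolated onto a 141×141 Cartesian grid at 1 mm.

Three modeling decisions deserve explanation:

* **Kernel and sign convention.**  $G$ is the zeroth-order Hankel kernel;
  all constant prefactors are dropped because the map is in arbitrary
  units.  The imaging kernel must be *phase-conjugate* to the physical
  propagation so that back-propagated phases cancel at the scatterer
  (time-reversal focusing).  We verified numerically that using the same
  Hankel kind in the simulator and the imaging operator focuses energy at
  the scatterer's antipode; the package therefore propagates forward with
  $H_0^{(1)}$ and images with $H_0^{(2)}$ (equivalently: one operator per
  time convention).  With measured data the choice amounts to picking the
  kind that matches the instrument's convention.
* **Conductivity weighting.**  The medium model uses the free-space
  permittivity (the antennas operate in air) and a tunable conductivity
  $\sigma \in \{0.01, 0.20, 0.40, 0.60\}$ S/m, giving
  $k_1 = \omega\sqrt{\mu_0 \varepsilon_0 (1 - j\sigma/\omega\varepsilon_0)}$.
  $\sigma_3 = 0.40$ S/m is the working default for segmentation and
  classification, the level reported optimal for lesion localization.
  With $\sigma > 0$ the kernel magnitude is multiplied by
  $e^{+|\mathrm{Im}\,k_1| r}$ ("attenuation compensation") so deep image
  points are not penalized; for $\sigma = 0$ the flag is bitwise a no-op.
* **Hankel evaluation.**  No installed numeric library evaluates cylinder
  functions at complex argument, so the package computes $H_0^{(1,2)}(z)$
  itself: the ascending series of $J_0$ and $Y_0$ for $|z| \le 11$ and the
  large-argument asymptotic expansion beyond, giving ~1e-9 relative
  accuracy over the arguments that occur (verified in the tests against
  frozen values from an independent implementation).  Distances from grid
  points to receivers are clamped at $10^{-6}$ m: boundary grid points can
  coincide with receiver positions, where the kernel is singular.

The reconstruction localizes a point scatterer to within one 3° azimuthal
bin, with a radial bias of a few millimeters toward the center at
$\sigma_3$ — the known cost of reconstructing with the free-space
permittivity.

## Adaptive segmentation (simplified PCNN)

Each pixel is a neuron.  With stimulus $S$ (the map min–max normalized to
$[0,1]$ over in-disc pixels), iteration $n$ computes

$$F = S,\qquad L = W * O[n-1],\qquad U = F(1 + \beta L),$$
$$O[n] = \mathbb{1}\{U > T[n-1]\},\qquad
  T[n] = e^{-\alpha_T} T[n-1] + V_T\, O[n],$$

with $\beta = 3$, $\alpha_T = 0.2$, $V_T = 20$, a 3×3 inverse-distance
linking kernel $W$ (zero center; the source work does not publish its
kernel), strict firing comparison, 32 iterations, and the fifth
iteration's binary mask used for localization.  The threshold recurrence
is written here in its standard causal form; the printed recurrence in the
source work indexes the threshold non-causally and cannot be implemented
as stated.

**Initial threshold.**  The published description of the iteration
behavior is not consistent with any initialization we could find for a
$[0,1]$ stimulus: with $T_0 = 0$ every neuron fires at iteration 1, the
$V_T$ boost then silences the lattice, and iterations 3–16 are *provably
empty* ($T \ge 20e^{-0.6} \approx 11$ at iteration 5 while
$U \le 1 + \beta \sum W \approx 21.5 S$ can only refire much later).  An
informative fifth iteration — which the whole localization procedure
depends on — requires the first firing wave to arrive there.  We therefore
default to $T_0 = 2$: the threshold decays to $2e^{-0.8} \approx 0.90$ at
iteration 5, so the first wave fires precisely the top-intensity structure
at the selected iteration, and subsequent waves descend the intensity
levels (the auto-wave behavior the method relies on).  $T_0$ is a
parameter; setting `t0 = 0` restores the all-fire-first behavior.

Lesion regions are 8-connected components of the selected mask with at
least `min_area = 5` pixels (suppressing speckle).  The *lesion region* is
the component containing the strongest stimulus — robust against rim
artifacts in reconstructed maps — falling back to the largest component
when none reaches `min_area`.  Its centroid row against the image center
row assigns the upper/lower zone; a centroid exactly on the center row
counts as upper (documented tie rule).

## Non-parametric thresholding

Each map is smoothed with a 2D Gaussian kernel, $\sigma = 30$ px on the
1 mm grid, truncated at $4\sigma$, with replicate (edge-value) padding —
implemented as an exact separable band-matrix convolution because the
kernel half-width (120 px) is comparable to the image itself.  Per breast,
Q1/Q2/Q3 of the in-disc smoothed intensities are computed with the
linear-interpolation quantile estimator (the common default in scientific
software; the source work does not name one).  The cohort threshold
averages the two group means of Q3,
$\theta = (\overline{Q3}_{NF+BF} + \overline{Q3}_{MF})/2$, and a breast is
called MF when its median Q2 exceeds $\theta$ (ties to NF+BF).  The
direction of the rule is configurable because the source work's own group
statistics (MF quartiles *below* NF+BF ones, yet MF declared above the
threshold, and a reported operating threshold of 1690 that is not the
average of the reported 1600/1500 group means) cannot be made mutually
consistent; we implement the rule exactly as stated and note that the
reported clinical operating point is not reproducible from the published
statistics.

### Why the threshold rule constrains the synthetic generator

Smoothing a disc-supported map with $\sigma = 30$ px dilutes intensity
near the rim, so the *within-map* distribution of every smoothed map is a
scaled copy of a fixed profile: $Q2 \approx 0.66\,b$ and
$Q3 \approx 0.80\,b$ for a map of level $b$.  The decision compares
per-breast Q2 against a Q3-based threshold, which is therefore biased
upward by a fixed factor $\approx 1.21$.  A short calculation shows that
for two *equal-spread* groups separated by 3 pooled standard deviations
this bias exceeds the separation margin for every parameterization — the
chain cannot recover such a cohort, mirroring the internal inconsistency
noted above.  The generator consequently models what makes the rule
workable: a *heterogeneous* NF+BF population (bounded arcsine-distributed
levels, SD 650 a.u., emulating the wide fatty-to-dense range of healthy
breasts) and a *tight* MF population (SD 195 a.u.) shifted upward by
`effect_size` pooled SDs.  With bounded distributions the groups' supports
are disjoint at `effect_size = 3` and the Q3-average threshold falls in
the gap with a margin of several hundred a.u. — recovery then measures the
pipeline, not sampling luck.  At `effect_size = 0` the two groups share a
location and classification accuracy is indistinguishable from chance.

Each MF map (and roughly half of the NF+BF maps, matching the share of
benign findings among with-finding breasts in the study roster) carries a
Gaussian lesion blob: $\sigma_{blob} = 4$ mm, amplitude $3\times$ the
breast level, placed 15–45 mm from the center away from the horizontal
midline, with its upper/lower zone recorded as ground truth.  The blob is
bright enough to be the unique top-intensity structure (so the PCNN
iteration-5 mask finds it) yet small enough to leave the quartiles
essentially untouched.

**What the generator does not emulate:** speckle and clutter of real
reconstructions, breast-shape asymmetry, fibroglandular texture,
multi-focal disease, patient-movement artifacts, or any coupling between
lesion presence and overall map level.  Passing the recovery tests
demonstrates the chain's correctness and its behavior under controlled
contrast; it does not certify clinical performance.

## Evaluation

Confusion counts with MF as the positive class;
sensitivity $= 100\,TP/(TP+FN)$ and specificity $= 100\,TN/(TN+FP)$.
Zone agreement is computed only over breasts with a single stated
reference zone ("More Areas" and "Not Available" entries are excluded).
The packaged roster fixture transcribes the 61-breast study table; its
derived statistics (61 breasts, 35 patients, rounded mean age 52, band
counts 23 and 38) match the published summary.  Note the published band
counts sum to the number of *breasts*, so the bands here count roster
rows, not patients.

## Numerical choices and degenerate inputs

* Quantile estimator: linear interpolation (`type = 7`); whiskers are
  Tukey fences at 1.5 IQR.
* Constant maps normalize to an all-zero stimulus with a warning; the
  PCNN then produces empty masks.
* Polar-to-Cartesian interpolation is bilinear in $(\rho, \phi)$ with
  azimuthal wrap-around; radii below the first ring (1 mm) clamp to it.
* Classification ties (Q2 exactly at $\theta$) go to NF+BF; zone ties
  (centroid on the center row) go to upper.
* All randomness (simulator noise, synthetic cohorts) is seeded;
  segmentation and reconstruction are fully deterministic.

## Problem sizes used by the test suite

The suite runs the geometry at full angular resolution but decimates the
frequency sweep (17 frequencies at 500 MHz for localization tests, 9 at
1 GHz for cancellation tests) and uses the study's cohort composition
(49 NF+BF + 11 MF) for recovery experiments; the PCNN
implementation-versus-reference equivalence uses 20 random lattices up to
12×12 over all 32 iterations, compared exactly.  These sizes keep the
full suite under a minute of compute while exercising every code path at
the study's parameter defaults.

## Known limitations

* The forward model is single-scattering in free space; quantitative
  dielectric reconstruction (inverse scattering) is out of scope.
* The reconstruction inherits the documented radial localization bias of
  free-space imaging.
* The classifier learns a single scalar threshold under supervision; no
  cross-validation or per-density calibration is provided.
* The published clinical operating point (81.82% sensitivity, 98%
  specificity, threshold 1690 a.u.) depends on recordings that are not
  deposited and on internally inconsistent published statistics; it is
  deliberately not reproduced, only the chain that would produce it.
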