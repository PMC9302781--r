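# mwibreast

Analysis chain for multi-bistatic **microwave breast imaging**: from
complex S21 scattering recordings to a malignant / non-malignant call per
breast, with lesion localization into upper/lower zones.

Microwave imaging exploits the dielectric contrast between healthy and
lesioned breast tissue.  A rotating receiver records the transmission
parameter S21 at 80 azimuthal positions for 10 transmitter positions
(five sections × two-member *doublets*) over 1–9 GHz.  The package
implements:

1. **Huygens-principle reconstruction** — doublet subtraction removes
   transmitter-independent artifacts, then the internal field is
   back-propagated from the receiver ring with a cylindrical-wave kernel
   and a conductivity-weighted complex wavenumber
   (k₁ = ω√(μ₀ε₀(1 − jσ/ωε₀)), σ ∈ {0.01, 0.20, 0.40, 0.60} S/m, with
   attenuation compensation e^{+|Im k₁|r}):

       E(ρ, φ; m; f) ∝ Σₙ ΔS21(n, m, f) · G(k₁ |ρₙ − ρ|)
       I(ρ, φ)       = Σₘ Σᵢ |E(ρ, φ; m; fᵢ)|²

   on a 1 mm / 3° polar grid, interpolated to a 141×141 Cartesian map.
2. **Simplified PCNN segmentation** — a pulse-coupled neural network
   (feeding F = S, linking L = W∗O, activity U = F(1+βL), firing
   O = [U > T], threshold T ← e^(−α_T)T + V_T·O with β = 3, α_T = 0.2,
   V_T = 20) produces one binary mask per iteration; the iteration-5 mask
   localizes the lesion region, assigned to the upper or lower zone.
3. **Quartile thresholding** — maps are smoothed (Gaussian σ = 30 px,
   replicate padding), summarized by per-breast quartiles, and classified
   by the median rule against the cohort threshold
   θ = (mean Q3 over NF+BF + mean Q3 over MF)/2.
4. **Evaluation** — confusion matrix (MF positive), sensitivity /
   specificity, and lesion-zone agreement.
5. **Synthetic data** — a Born-type S21 simulator on the device geometry
   and a cohort generator with controlled group contrast, so the full
   chain is testable without the (undeposited) clinical recordings.  The
   packaged roster fixture transcribes the 61-breast study table.

See `vignettes/microwave-lesion-detection.Rmd` for the models, parameter
choices and design rationale.

## Worked example

Simulate a phantom with one inclusion at ρ = 30 mm, φ = 90° (upper zone),
reconstruct at σ₃ = 0.40 S/m, and localize:

```r
library(mwibreast)

g  <- build_geometry(freq_step = 5e8)          # 80 receivers, 17 frequencies
ph <- phantom_spec(inclusions = list(
        list(rho = 0.03, phi = 90, radius = 0.005, amplitude = 1 + 0i)))
s  <- simulate_s21(ph, g, noise_sd = 0)

pol <- reconstruct_map(s, conductivity = 0.40, cartesian = FALSE)
map_peak(pol)
#> $rho
#> [1] 0.026
#> $phi
#> [1] 90

reg <- localize_lesion(polar_to_cartesian(pol))   # PCNN iteration-5 mask
reg$zone
#> [1] "upper"
```

The peak azimuth matches the inclusion exactly; the radius is biased a few
millimeters toward the center — the documented cost of reconstructing with
the free-space permittivity.

Run the full synthetic-cohort pipeline at the study composition
(49 NF+BF + 11 MF breasts, group separation 3 pooled SDs):

```r
res <- run_pipeline(pipeline_config(n_nfbf = 49, n_mf = 11,
                                    effect_size = 3, seed = 1))
res$metrics
#> sensitivity specificity
#>         100         100
res$zone_agreement$agreement
#> [1] 1
res$confusion
#>           gold MF  gold NF+BF
#> pred MF        11           0
#> pred NF+BF      0          49
```

All 11 malignant-finding breasts are recovered, no false positives, and
every predicted lesion zone matches the generated ground truth.

A thin CLI wraps the same functions
(`inst/cli/mwibreast simulate | reconstruct | segment | classify |
evaluate | roster-stats | run`).

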