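# memloc

Quantitative analysis of how small amphipathic molecules — indole-ring
metabolites of the serotonin pathway (tryptophan, 5-hydroxytryptophan,
serotonin, N-acetylserotonin, melatonin) and compounds like them —
partition into lipid membranes and perturb them. The package is aimed at
membrane biophysicists combining several complementary readouts on model
membranes, and implements the analysis layer for five of them:

| readout | question | core functions |
|---|---|---|
| ²H NMR of chain-perdeuterated lipid | how ordered are the acyl chains? | `depake()`, `smoothed_profile()`, `average_order()` |
| ¹H MAS NOESY buildups | at what depth does the molecule sit? | `fit_spin_pair()`, `build_depth_profile()` |
| FCS of labelled vesicles | do vesicles associate (grow)? | `fit_fcs()`, `radius_from_tau()` |
| TCSPC fluorescence lifetimes | what fraction is membrane-bound? | `fit_multiexp()`, `bound_fraction_standard()`, `bound_fraction_tryptophan()` |
| MD-style coordinate ensembles | depth, ring orientation, H-bonds, hydration | `min_distance_distribution()`, `ring_orientation_distribution()`, `hbond_count()`, `water_penetration_profile()` |

The models in brief: ²H powder patterns are dePaked (non-negative
least-squares inversion of the explicit orientational average) and
converted to per-carbon order parameters via
S\_CD = Δν / ((3/2)·χ) with χ = 167 kHz; NOESY cross-peaks are fitted to
the two-spin solution a(τ\_m) = ½·e^(−ρτ\_m)(e^(στ\_m) − e^(−στ\_m)) and
the rates σ\_g mapped to depth by A(z) = Σ\_g σ\_g·p\_g(z) over lipid
functional-group z-distributions; FCS traces are fitted to the
two-component 3D diffusion + triplet model
G(τ) = [1 + f/(1−f)·e^(−τ/τ\_t)]·Σᵢ gᵢ(1+τ/τ\_Di)⁻¹(1+τ/(a²τ\_Di))^(−1/2) + bl
with R\_H = 0.58 nm · τ\_D/27 µs against the rhodamine B standard; TCSPC
decays are fitted by Poisson maximum likelihood and bound fractions read
off the relative amplitudes of membrane-induced lifetime components, with
a depletion correction for two-lifetime fluorophores such as tryptophan.

A synthetic-data module (`make_powder_spectrum()`, `make_noesy_volumes()`,
`make_fcs_trace()`, `make_decay()`, `make_bilayer_frames()`) generates
every input with known ground truth, so the full pipeline is testable
without instrument data. See the vignette
(`vignettes/membrane-localization-methods.Rmd`) for models, conventions
and numerical choices.

## Worked example

Order parameters from a synthetic powder spectrum, and vesicle sizing from
synthetic FCS traces:

```r
library(memloc)

## 2H NMR: plateau-plus-decay chain order, 0.5% noise
sp   <- make_powder_spectrum(c(rep(0.21, 7), seq(0.21, 0.02, length.out = 9)[-1]),
                             noise_sd = 0.005, seed = 42,
                             n_points = 2401, freq_range_khz = 60)
dep  <- depake(baseline_and_symmetrize(sp), tolerance = 0.5)
prof <- smoothed_profile(dep)
head(prof, 4)
#>   carbon      s_cd
#> 1      2 0.2201389
#> 2      3 0.2099800
#> 3      4 0.2099800
#> 4      5 0.2099800
average_order(prof)
#> [1] 0.1492

## FCS: four replicate traces of dye + vesicle-bound dye, 2% noise
p    <- fcs_params(f = 0.1, tau_t = 2e-6, tau_d1 = 27e-6, tau_d2 = 2.7e-3,
                   g1 = 0.6, g2 = 0.4, a = 5)
fits <- lapply(1:4, function(i)
  fit_fcs(make_fcs_trace(p, noise_frac = 0.02, seed = i), fixed = "a"))
replicate_summary(fits)
#> R_H = 58.1 +/- 0.69 nm (n = 4)
```

The recovered per-carbon order parameters track the generating profile
(plateau 0.21, decaying to 0.02 at the terminal methyl) and the
deuteron-weighted average (0.149) matches the ground-truth mean. The
vesicle hydrodynamic radius follows from the slow diffusion time through
the rhodamine calibration: τ\_D2 = 2.7 ms is 100× the 27 µs standard, so
R\_H ≈ 58 nm.

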