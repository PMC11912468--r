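---
title: "Methods: quantifying small-molecule membrane localization and ordering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying small-molecule membrane localization and ordering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memloc)
```

memloc bundles the quantitative analysis behind a recurring experimental
design in membrane biophysics: asking where a small amphipathic molecule
(here, indole-ring metabolites of the serotonin pathway) sits in a lipid
bilayer and what it does to the bilayer once there. Five largely
independent readouts are covered — deuterium NMR chain order, NOESY
cross-relaxation depth mapping, FCS vesicle sizing, TCSPC lifetime binding
assays, and trajectory geometry statistics — each behind a small set of
functions, plus generators that synthesize every input with known ground
truth. This vignette documents the models, the numerical choices, and what
the synthetic-data tests do and do not demonstrate.

## Deuterium NMR: from powder patterns to order profiles

A chain-perdeuterated lipid in an unoriented multilamellar dispersion gives
a superposition of axially symmetric quadrupolar powder patterns, one per
CD segment. A segment with order parameter $S_{CD}$ contributes, at bilayer
orientation $\theta$, a doublet at
$\pm\tfrac{3}{4}\chi S_{CD}\,\tfrac{3\cos^2\theta - 1}{2}$, where $\chi$ is
the static quadrupolar coupling constant. We fix $\chi = 167$ kHz for C–D
bonds (configurable; a value in the 165–170 kHz range is standard). Two
conversion conventions exist and are easy to mix up; the package uses them
in exactly one place each:

* raw powder spectra: the dominant 90° edges ("horns") of one segment are
  separated by $\tfrac{3}{4}\chi S_{CD}$;
* dePaked (0°-oriented-equivalent) spectra: the doublet splitting is
  $\Delta\nu = \tfrac{3}{2}\chi S_{CD}$, so $S_{CD} = \Delta\nu /
  (\tfrac{3}{2}\chi)$.

`make_powder_spectrum()` computes the powder average by quadrature over
$u=\cos\theta$ on a uniform grid ($10^4$ points by default; uniformity in
$u$ carries the $\sin\theta$ weight), deposits each orientation's doublet
onto the frequency grid with linear interpolation, and applies Gaussian
line broadening. The quadrature agrees with the analytic lineshape to well
below the default broadening; we chose it over the closed form for
readability and because the same operator is reused for inversion.

`depake()` inverts the explicit forward transform (orientational average
followed by line broadening) by non-negative least squares
(Lawson–Hanson, via `pracma::lsqnonneg`). This choice fell out of
experimentation: multiplicative (Richardson–Lucy) and accelerated
projected-gradient iterations both stall around $10^{-2}$–$10^{-3}$
relative residual on this operator, whereas the active-set solver reaches
the least-squares floor (typically $10^{-4}$ or better on noiseless input)
in under a second on a ~600-point half grid, and returns the physically
expected near-stick doublets. Non-negativity is the only regularization;
for noisy spectra the `tolerance` argument (the acceptance threshold on the
relative residual) should be relaxed to the noise level, since the residual
then reflects noise rather than model error. Inversion operates on the
non-negative-frequency half of a `baseline_and_symmetrize()`d spectrum;
a linear baseline is estimated from the outer 5% of the frequency range.

`smoothed_profile()` implements the standard monotone ("smoothed")
order-profile construction for unresolved spectra: assume order decreases
toward the terminal methyl, partition the cumulative half-spectrum integral
into per-carbon slices with areas proportional to deuteron counts (2 per
methylene, 3 for the terminal CD$_3$, which owns the smallest-splitting
slice), and convert each slice's intensity-weighted mean splitting to
$S_{CD}$. Slice weighting recipes differ slightly across the literature;
the equal-area-per-deuteron choice here is the simplest one consistent with
integral conservation, and recovery tests show per-carbon errors of a few
percent dominated by grid discretization at the terminal methyl (hence the
finer default grids in the examples). The C2 inequivalence is ignored — a
single averaged value per carbon — and `average_order()` reports the
deuteron-weighted mean.

## NOESY cross-relaxation and depth mapping

Magnetization exchange between one metabolite proton and one lipid
functional group is modelled as an isolated two-spin system: the cross-peak
volume, normalized to the diagonal volume at the shortest mixing time (the
reference magnetization; 0.1 ms in the default series 0.1/100/200/300/500
ms), builds up as
$$a(\tau_m) = \tfrac12 e^{-\rho\tau_m}\left(e^{\sigma\tau_m} -
e^{-\sigma\tau_m}\right),$$
with cross-relaxation rate $\sigma$ and leakage rate $\rho$.
`fit_spin_pair()` fits both by Levenberg–Marquardt least squares, seeding
$\sigma$ from the initial buildup slope (which equals $\sigma$ exactly).
$\rho$ is fitted per pair rather than shared across a proton's series;
group protons can differ substantially in leakage, and the per-pair choice
is robust at the cost of two parameters per curve. Spin diffusion beyond
the pair is deliberately ignored — at the mixing times used, multi-spin
pathways bias rates systematically, which is a recognized limitation of the
spin-pair model, not of its implementation.

`build_depth_profile()` converts rates to a localization estimate:
$A(z) = \sum_g \sigma_g\, p_g(z)$, where $p_g$ is lipid group $g$'s
z-distribution in the membrane (unit integral, $z=0$ at the mean terminal
CH$_3$ position). The amplitude carries rate units, so $A(z)$ is a
proximity-weighted density, not a probability. Rates are not divided by
the group proton count by default (`proton_counts` enables it): volumes
from well-separated group resonances already aggregate the group's
protons, and the un-normalized sum matches how such depth maps are usually
presented. The packaged group distributions
(`synthetic_group_distributions()`, also under `inst/extdata/`) are
synthetic Gaussians with field-plausible means and widths — a labelled
stand-in, because measured distributions belong to whichever simulation or
scattering study a user trusts; `load_group_distributions()` renormalizes
and re-references any substitute table. The z grid is 0.5 Å with linear
interpolation for resampling.

## FCS: two-component diffusion with a triplet

The autocorrelation model is
$$G(\tau) = \left[1 + \tfrac{f}{1-f}e^{-\tau/\tau_t}\right]
\sum_{i=1,2} g_i \left(1+\tfrac{\tau}{\tau_{Di}}\right)^{-1}
\left(1+\tfrac{\tau}{a^2\tau_{Di}}\right)^{-1/2} + bl,$$
the standard two-component three-dimensional diffusion form with triplet
fraction $f$, triplet lifetime $\tau_t$, diffusion times
$\tau_{D1}\le\tau_{D2}$ with amplitudes $g_1,g_2$, structure parameter $a$
(the $z_0/w_0$ aspect ratio of the Gaussian focal volume) and background
$bl$. Amplitudes are not constrained to sum to one; fractions should be
reported as $g_i/\sum g$. The structure parameter is rarely knowable from
a trace alone and should be fixed from instrument calibration
(`fit_fcs(..., fixed = "a")`); $\tau_{D1}$ can likewise be fixed at the
free-dye value. Fitting is Levenberg–Marquardt with uniform weights on a
log-spaced lag grid, with log/logit transforms enforcing positivity and
$f\in[0,1)$; default starting values come from trace heuristics (tail
background, short-lag amplitude, lags at one- and three-quarter decay).

Diffusion times convert to hydrodynamic radii through the Stokes–Einstein
proportionality at fixed geometry, temperature and viscosity:
$R_H = R_{H,\mathrm{cal}}\,\tau_D/\tau_{D,\mathrm{cal}}$, with the free
rhodamine B calibration $\tau_D = 27\,\mu$s, $R_H = 0.58$ nm as default.
Temperature/viscosity corrections are out of scope since calibration and
samples are measured under the same conditions. `replicate_summary()`
reports mean ± SEM over replicate measurements.

The synthetic trace generator adds Gaussian noise whose sd follows the
local correlation amplitude (plus a 5% floor of the zero-lag amplitude);
real correlator noise is lag-correlated and count-rate dependent, so
recovery statistics under this model demonstrate estimator correctness,
not instrument-grade precision.

## TCSPC lifetimes and bound fractions

Decay histograms are Poisson, so `fit_multiexp()` maximizes the Poisson
likelihood rather than least squares. Amplitudes are profiled out: for
fixed lifetimes (and IRF position), the optimal non-negative component
weights are computed by monotone multiplicative EM updates, leaving a
search over at most four parameters (up to three log-lifetimes plus the
IRF center), run from three deliberately different starting ladders with
the best likelihood kept. In joint optimization the same fits routinely
stalled in amplitude-compensated local minima; profiling removed that
failure mode. With `irf_width_ps > 0` each component is an analytic
exponential–Gaussian convolution; with 0 a pure multi-exponential is
fitted from `tail_start_ns` and amplitudes are extrapolated back to the
decay origin. Reported amplitudes are standard TCSPC relative amplitudes
(the $\alpha_k$ of $\sum_k \alpha_k e^{-t/\tau_k}$, normalized to 1),
which equal population fractions when radiative rates are shared.
Lifetime pairs closer than a factor of 2 are flagged unidentifiable —
recovery studies here degrade sharply below ratio ~4, consistent with
general TCSPC practice.

Bound fractions follow from amplitude bookkeeping. For a fluorophore that
is single-exponential in buffer, `bound_fraction_standard()` sums the
amplitudes of vesicle-sample components whose lifetime matches no buffer
component; matching uses a relative window (30% default) because
membrane-bound lifetimes vary between compounds. For tryptophan, which has
two buffer lifetimes (~0.65 and ~3 ns) with the short one overlapping the
membrane-bound short lifetime, `bound_fraction_tryptophan()` adds a
depletion correction: binding removes molecules from the aqueous pool, so
the remaining aqueous amplitudes shrink proportionally and the short/long
amplitude ratio rises even with zero binding into the short-lifetime pool.
Measuring the aqueous depletion by the long (3 ns) amplitude — which has
no membrane counterpart — the binding-induced rise is
$\Delta a_s = a'_s - a_s\,(a'_l/a_l)$ (primes: vesicle sample), and the
bound fraction is $a_{\mathrm{new}} + \Delta a_s$. This is the minimal
algebra consistent with proportional depletion; it returns exactly the
injected bound share on constructed amplitude sets and exactly zero when
the vesicle sample equals the buffer sample.

## Trajectory geometry

All geometry is referenced to the bilayer center plane: depths are
$|z - z_c|$ with $z_c$ the per-frame mean lipid z
(`bilayer_center_z()`), not 3D distances to a point, because the analyzed
bilayers are planar. Leaflets are not distinguished. z is wrapped into
the primary box before centering.

* `min_distance_distribution()`: per frame and ligand copy, the minimum
  over heavy atoms of the depth; histogrammed in 0.05 nm bins and
  normalized by the most populated bin.
* `ring_orientation_distribution()`: angle between the indole long axis
  and the bilayer normal. "The vector formed by C2 and C5–C6" is
  implemented as C2 → midpoint(C5, C6), which spans the ring's long axis;
  C2→C5 or C2→C6 are available via `axis` for sensitivity checks.
* `hbond_count()`: a bond requires donor–acceptor distance ≤ 0.35 nm and
  donor–H⋯acceptor angle ≥ 135° by default — common trajectory-analysis
  cutoffs, both configurable and echoed in the output since conventions
  differ between tools.
* `water_penetration_profile()`: per-frame histograms of water-oxygen
  depth, averaged over frames.

Only user-designated frame ranges are analyzed (`frames` argument);
equilibration detection is the user's responsibility.

## The synthetic-data module

`make_bilayer_frames()` builds flat-bilayer ensembles: mirrored
pseudo-lipid beads (so the midplane is exact by construction), rigid
indole-template ligands with Gaussian-sampled insertion depths and
ring-axis tilts, and optional water beads with an exclusion zone and a
depletion band. Undulations, lipid internal structure, and realistic
hydration are deliberately absent: every analyzed statistic is z-referenced,
so a flat bilayer exercises the full code path while keeping ground truth
exact. Likewise, the TCSPC generator's Gaussian IRF (default sd 50 ps),
the FCS noise model, and the NMR Gaussian line broadening are idealized.
Passing recovery tests therefore establishes that the estimators invert
their own forward models at realistic noise levels — it does not establish
robustness to instrument artifacts (detector afterpulsing, correlator bias,
colored IRFs, spin diffusion) that the generators do not emulate.

Every generator takes a seed and reproduces its output bit-identically;
noiseless outputs match their closed forms to near machine precision
(tested against independent oracles: direct formula evaluation, numerical
integration of the two-spin relaxation ODE, brute-force geometry loops).

## Problem sizes and reproduction

The test suite and `scripts/acceptance.R` run everything at desk scale,
chosen so the full pipeline (generation, fitting, recovery statistics)
completes in about a minute per stage: 100 FCS traces at 2% noise for the
$\tau_{D2}$ recovery median, a 2401-point spectrum over ±60 kHz for the
dePake round trip (the signal region of the ±250 kHz instrument window,
gridded finely enough to resolve the terminal-methyl splitting), 50 noisy
NOESY replicates, $10^5$-count decays (9 replicates for the three-component
median), and 60-frame × 20-ligand bilayer ensembles. The acceptance script
reports recovered values and recovery errors as JSON;
`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
reproduces them.

## Known limitations

* The spin-pair model understates $\sigma$ changes when spin diffusion is
  active; a full relaxation-matrix treatment is out of scope.
* The smoothed order profile assumes strict monotonicity; specific
  labelling or resolved spectra should use `extract_splittings()` instead.
* Discrete multi-exponential lifetime models are a coarse description of
  heterogeneous membrane environments; bound fractions from them are
  comparative estimates, not thermodynamic binding constants.
* The depth map inherits whatever bias the supplied group distributions
  carry, and the packaged distributions are synthetic placeholders.
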