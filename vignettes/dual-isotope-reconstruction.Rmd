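---
title: "Dual-isotope SPECT reconstruction with Monte Carlo scatter correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-isotope SPECT reconstruction with Monte Carlo scatter correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Simultaneous Tl-201/Tc-99m myocardial perfusion SPECT acquires a stress
(Tl-201, ~72 keV Hg X-rays) and a rest (Tc-99m, 140 keV) study in one scan.
Its Achilles heel is cross-talk: 140 keV photons that Compton-scatter in the
patient can lose enough energy to be detected inside the 15% window centred
on 72 keV, contaminating the Tl-201 data and washing out perfusion defects.
A single scatter cannot do this — a 140 keV photon retains at least
90.4 keV after one Compton interaction — so the contamination is made of
second- and higher-order scatter, which is broad, smooth and impossible to
remove by window subtraction alone.

`dualspect` implements a three-step reconstruction that corrects this
cross-talk with an accelerated Monte Carlo (MC) simulator:

1. **Tc-99m reconstruction.** OS-EM with attenuation, distance-dependent
   collimator response and MC self-scatter correction reconstructs the
   140 keV window; the result approximates the scatter-free Tc-99m activity.
2. **Down-scatter simulation.** The reconstructed Tc-99m volume is fed to
   the same MC engine, which transports 140 keV photons through the
   attenuation map and scores the expected counts they deposit inside the
   Tl-201 window — the down-scatter estimate.
3. **Tl-201 reconstruction.** OS-EM on the Tl-201 window, with the frozen
   down-scatter estimate added to the Tl-201 self-scatter estimate in the
   forward model.

# The reconstruction model

OS-EM iterates the multiplicative update per ordered subset $S$:

$$x \leftarrow x \cdot
  \frac{A_S^{T}\!\left(y_S / (A_S x + s_S + \varepsilon)\right)}{A_S^{T} 1},$$

where $A$ is the system model, $y$ the measured counts and $s$ the additive
projection-domain scatter term. Subsets interleave views (subset $i$ takes
views $i, i+S, \dots$) and are visited in bit-reversed order for angular
balance; the guard is $\varepsilon = 10^{-10}\,\overline{y}$; the initial
estimate is a uniform positive volume scaled so its total forward counts
match the data. The final volume is smoothed with a separable 3-D Gaussian
post-filter (default FWHM 0.9 cm).

**Projector.** $A$ is rotation based: for each view the volume is resampled
in-plane (bilinear, exact index permutation at multiples of 90°) so the
detector normal aligns with a grid axis, then detector-parallel planes are
swept from far to near. Each plane's emission is attenuated over half its
own thickness and the accumulator over full plane steps (Beer–Lambert,
$\mu$ interpolated log-log from a material table rescaled to the window
energy), and the accumulator is diffused incrementally so that a plane at
distance $d$ from the collimator face ends up blurred by the Gaussian PSF
with FWHM$(d) = \text{intercept} + \text{slope}\cdot d$ (defaults
3.8 mm + 0.0445·d, representative LEHR figures). The back projector is the
exact adjoint — same interpolation, same kernels, reverse order — which the
test suite verifies to $10^{-6}$ relative error; this adjointness is what
makes the OS-EM update well behaved.

**Numerical choices.** Incremental diffusion accumulates pending variance
and applies a kernel once it exceeds 0.15 px²; kernels are variance-exact
(a three-tap kernel below 0.25 px², otherwise a bin-integrated Gaussian
whose width is tuned by fixed-point iteration), so the accumulated blur of
every plane matches its nominal PSF variance exactly. The composition of
many small non-negative kernels differs from a one-shot Gaussian only in
the far tails (discrete-diffusion high-frequency leakage), which the test
suite bounds at 1% RMS for smooth plane sources. Bilinear rotation
conserves smooth compact sources to 0.5% but wobbles pointwise by a few
percent at diagonal angles; the wobble cancels between the forward and
adjoint passes of the ratio update.

# The Monte Carlo engine

The engine estimates scatter expectations, not noise realisations, with
heavy variance reduction:

- **Coarse grid.** Activity is block-summed and the attenuation map
  block-averaged by the coarse factor (default 2; 64³ → 32³). Scatter is
  smooth, so the folding loses little and cuts tracking cost.
- **Forced detection.** Emission sites are sampled proportional to the
  activity; photons get isotropic directions; free paths are sampled by
  Woodcock tracking against $\mu_{total}(E)$; interaction types are chosen
  by the Compton/photoelectric split; Compton angles come from Kahn
  rejection sampling of the Klein–Nishina density. After every scatter (up
  to order 3 by default) the expected contribution to *every* view is
  scored: the Klein–Nishina density towards the detector direction, times
  the transmission along the exit path at the scattered energy, times the
  probability that the Gaussian-blurred measured energy (9.9% FWHM at
  140 keV, scaling as $\sqrt{E}$) falls inside the scoring window.
- **Energy handling.** Material attenuation is carried as 140 keV Compton
  and photoelectric components and rescaled analytically (Klein–Nishina
  total cross-section ratio, $E^{-3}$) — the same laws that generate the
  default material table, which anchors soft tissue/lung/bone/water at
  standard 140 keV values. Exit transmissions use per-view precomputed maps
  evaluated at the scoring-window centre (photons scored in a 15% window
  are within a few percent of its centre), sampled by in-plane bilinear
  interpolation on the nearest axial slab — consistent with the coarse-grid
  resolution of the estimate.
- **Normalisation.** Unscattered (order-0) scores accumulate a primary
  estimate; the scatter estimate is scaled so these MC primaries match the
  analytic projector's totals. This makes $s$ exactly unit-consistent with
  $A x$ in the OS-EM denominator, for data generation and correction alike,
  independent of absolute detector efficiency.

**Intermittent updates.** Iteration 1 runs with zero self-scatter; the MC
estimate is recomputed from the current volume at the start of iterations
2…(1 + `scatter_iters`) and then frozen. The down-scatter term is never
recomputed during Tl-201 iterations — it derives from the completed Tc-99m
volume. Every source of randomness is seeded; identical seeds give
bitwise-identical estimates and reconstructions.

# The digital phantoms

The cardiac torso phantom is a stylised parametric anatomy: a body
ellipsoid, two lung ellipsoids, a liver ellipsoid, a spine cylinder and a
half-ellipsoid left-ventricular shell (outer semi-axes 45/45/60 mm, 12 mm
wall, base cut 20 mm above the centre) with its cavity. It reproduces the
four standard activity configurations (relative concentrations per voxel,
e.g. Tl-201 50/3/2/3/3 and Tc-99m 180/6/18/90/6 for the hot-liver
configuration) and their anterior/inferior/septal defects at 20–40% of
myocardial activity, each defect an angular sector of the shell (default
60° × 20 mm — the published description gives position and fraction only,
so the extent is a declared default, not an inferred one). Organ masks are
disjoint by construction and validated; overlapping ellipsoids are rejected.
A Jaszczak-style water cylinder with a fillable cardiac insert supports the
physical-phantom filling scheme (compartment activities in MBq, converted
to concentrations by voxelised compartment volumes).

`simulate_study()` produces the three datasets of the evaluation protocol —
the Tc window (primaries + self-scatter), the dual-study Tl window
(primaries + self-scatter + down-scatter) and a pure Tl study without the
down-scatter term — at 64 views, 64×64 bins of 6.6 mm, scales each window
to its target totals (defaults 76/80/10 Mcts) and adds Poisson noise. The
per-window scale factors are recorded so the down-scatter estimate can be
converted between Tc- and Tl-window count units during reconstruction; this
relative calibration is the information a real simultaneous acquisition
provides for free. The 128³/3.3 mm generation pathway is supported through
`collapse_projections()`; it made no measurable difference to the contrast
results here, so the default generates at the reconstruction grid directly.

**What the generator does not emulate.** NURBS anatomy, cardiac/respiratory
motion, septal penetration and — deliberately — collimator lead X-ray
fluorescence. The lead X-rays matter for fidelity to the published count
levels: the published window totals imply that ~90% of the dual-study
Tl-window counts are contamination, whereas patient-only Compton scatter
from these activity ratios produces ~25–30%. Since the correction under
study (like this package) corrects patient scatter only, the published gap
between corrected-dual and pure-Tl contrast includes an uncorrectable lead
X-ray component this simulation does not reproduce; passing tests therefore
show the correction works for patient scatter, not that real cameras have
no other contamination.

# Evaluation

Contrast follows the equal-area-ROI measure
$(C_{myo} - C_{region})/C_{myo}$ from summed counts on the short-axis slice
where the defect is best visible (deterministically: the slice maximising
the healthy-myocardium minus defect mean of the image). ROIs are machine
placed from the known phantom geometry — defect pixels nearest the defect
centroid, healthy-wall pixels nearest the diametrically opposite mid-wall
point, cavity pixels nearest the cavity centre — trimmed to equal areas
(requested 15 px; on a 6.6 mm grid the defect mask limits this to ~10 px).
On the true activity volume this measure returns exactly one minus the
defect fraction. Projection profiles are band means of configurable width
(default 10 pixels).

# Problem sizes and parameters used by the shipped checks

The test suite and the acceptance script run the full published protocol —
64³ voxels at 6.6 mm, 64 views, 10 iterations × 8 subsets, coarse factor 2,
0.9 cm post-filter, window totals 80/76/10 Mcts — with the published photon
budgets (10⁵/10⁶ for self-scatter, 10⁵–10⁷ for down-scatter). The only
scaled-down element is the data-generation scatter budget (2×10⁶ photons
per term), chosen so the simulated expectations are smooth at desk-scale
runtimes; property tests use a 32³ replica of the same anatomy. Known
consequences of the scale: the 12 mm wall spans two voxels, so
partial-volume losses on reconstructed contrasts are larger than with
finer anatomy and hand-placed ROIs, and measured defect contrasts sit a
few hundredths below their noise-free ideals (the pure-Tl anterior average
is the most affected quantity).

# Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `iterations`, `subsets` | 10, 8 | – | OS-EM schedule; chosen where contrast stops improving |
| `scatter_iters` | 2 | iterations | leading iterations that refresh the MC self-scatter estimate |
| `photons` | 1e5 | photons | self-scatter budget per update |
| down-scatter `photons` | 1e6 | photons | budget for the Tc→Tl estimate (noisier target, more photons) |
| `coarse` | 2 | – | MC grid folding factor |
| `max_order` | 3 | – | Compton orders tracked (≥2 required for down-scatter) |
| `postfilter_cm` | 0.9 | cm | 3-D Gaussian post-filter FWHM |
| `eres_fwhm140` | 0.099 | fraction | detector energy resolution at 140 keV |
| collimator | 3.8 mm + 0.0445·d | mm | Gaussian PSF FWHM vs distance (LEHR-like) |

# Known limitations

- Single-line emission models (72 keV for Tl-201, 140 keV for Tc-99m); the
  minor 167 keV Tl-201 line and the full Hg X-ray complex are collapsed.
- Compton + photoelectric only; coherent scattering and Doppler broadening
  are ignored (standard for fast scatter estimators at 70–140 keV).
- No septal penetration, lead X-rays, backscatter compartment or dead time.
- The stylised anatomy is not NCAT: absolute contrast values carry a
  partial-volume penalty at 6.6 mm sampling, which is why the shipped
  acceptance checks compare with generous scaled-down tolerances.
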