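# dualspect

Simultaneous Tl-201/Tc-99m dual-isotope myocardial perfusion SPECT
reconstruction with Monte Carlo (MC) scatter and cross-talk correction, in R
with a compiled (Rcpp) projector and photon-transport core.

## The problem

In simultaneous dual-isotope imaging, 140 keV Tc-99m photons that
Compton-scatter twice or more in the patient are detected inside the 15%
energy window centred on 72 keV used for Tl-201, contaminating the Tl-201
study and hiding perfusion defects. `dualspect` reconstructs such studies in
three steps:

1. **Tc-99m OS-EM reconstruction** — ordered-subsets expectation
   maximisation with a rotation-based projector, incremental attenuation
   weighting, a distance-dependent Gaussian collimator PSF
   (FWHM(d) = intercept + slope·d) and MC self-scatter correction refreshed
   only during the first iterations (intermittent scatter modelling);
2. **MC down-scatter simulation** — the reconstructed Tc-99m volume is
   transported by a forced-detection MC engine (Woodcock tracking,
   Klein–Nishina sampling, coarse-grid folding, configurable photon budget)
   and scored in the Tl-201 window;
3. **Tl-201 OS-EM reconstruction** — the frozen down-scatter estimate is
   added to the Tl-201 self-scatter term in the OS-EM denominator
   `A x + s`.

The OS-EM update per subset `S` is

    x <- x * [ A_S' ( y_S / (A_S x + s_S + eps) ) ] / A_S' 1

Stylised digital phantoms (a parametric cardiac torso with configurable
organ activities and 20–40% wall defects, and a Jaszczak-style cylinder
with a cardiac insert) simulate complete dual-isotope studies with Poisson
noise, and the analysis module measures the equal-area-ROI contrast

    contrast = (C_myocardium - C_region) / C_myocardium

on the short-axis slice where the defect is best visible, plus band
profiles through down-scatter projections. See the vignette
(`vignettes/dual-isotope-reconstruction.Rmd`) for the model, assumptions
and numerical choices.

## Worked example

Simulate the hot-liver phantom configuration with an anterior defect at 20%
of myocardial activity, reconstruct the Tc-99m window with the optimised
parameters (10 iterations, 8 subsets, 2 scatter-update iterations, 1e5
photons, coarse factor 2, 0.9 cm post-filter) and measure its contrasts:

```r
library(dualspect)

phantom <- build_cardiac_phantom(cardiac_phantom_spec(3))
study   <- study_spec()                   # 64 views, 64x64, 15% windows
sim     <- simulate_study(phantom, study, seed = 42L)

tc <- osem(sim$tc, phantom$mu_map, study$geometry, study$collimator,
           recon_config(iterations = 10, subsets = 8, scatter_iters = 2,
                        photons = 1e5, postfilter_cm = 0.9, seed = 1L))
contrast_analysis(tc$volume, phantom, defect = "anterior")
#> <contrast_result> slice 39: myocardium-defect 0.718, myocardium-LV 0.971
```

The defect ROI retains 0.718 contrast against the healthy wall (the true
value in the phantom is 0.8; reconstruction blur accounts for the rest) and
the ventricular cavity is nearly fully resolved (0.971 vs a true 0.967).
Step 2 and 3 complete the dual study:

```r
dual <- reconstruct_dual(sim$tc, sim$tl_dual, phantom$mu_map,
                         study$geometry, study$collimator,
                         recon_config(seed = 1L), recon_config(seed = 2L),
                         ds_mc = mc_config(photons = 1e6, seed = 3L))
contrast_analysis(dual$tl, phantom, defect = "anterior")
#> <contrast_result> slice 39: myocardium-defect 0.685, myocardium-LV 0.932
```

With the down-scatter correction the Tl-201 defect contrast (0.685) is
restored close to the pure-Tl-201 level; without it the same data
reconstruct to visibly lower contrast.

A thin command-line interface wraps the same functions
(`inst/cli/dualspect`): `phantom build`, `phantom simulate`,
`recon single|dual`, `mc downscatter`, `analyze contrast`, `pipeline run`.

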