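# probead

Release kinetics, micrograph morphometry and wall-material optimization
for probiotic encapsulation beads.

## The problem

Probiotic cells are protected from gastric conditions by encapsulating
them in hydrogel beads (alginate crosslinked with Ca²⁺, typically blended
with prebiotic agavins and whey protein). Assessing a formulation means
answering three quantitative questions:

* **Release kinetics** — how do cells leave the bead during simulated
  oral/gastric/intestinal digestion? For a fraction released
  f(t) = Mt/M∞ the classical models are zero-order (f = k·t), Higuchi
  (f = k·√t on 0.1 < f < 0.6), Korsmeyer–Peppas (f = k·tⁿ) and
  Peppas–Sahlin (f = k₁tᵐ + k₂t²ᵐ, separating Fickian diffusion from
  polymer relaxation). The exponent n classifies transport (n ≤ 0.43
  Fickian, 0.43 < n < 0.85 anomalous, n ≥ 0.85 Case II, n > 1 Super
  Case II for spheres); the Damköhler number Da = growth rate / release
  rate says whether the bead traps cells (Da > 1) or leaks them faster
  than they grow (Da < 1); the *equilibrium point* is the time at which
  released and retained viable cells are equal.
* **Morphometry** — size/shape descriptors, skeletonization of the
  internal network, GLCM texture features (ASM, contrast, correlation,
  IDM, entropy), box-counting fractal dimension, gliding-box lacunarity
  and the SDBC grayscale fractal dimension of bead micrographs.
* **Design optimization** — 3² factorial designs over (agavin %, whey %),
  quadratic response surfaces, one-way ANOVA with Tukey letters, and
  multi-response desirability optimization (maximize area, circularity,
  solidity; minimize perimeter).

Since encapsulation studies rarely deposit raw curves or micrographs, the
package ships a synthetic-data module (release/growth curves, paired
medium/in-bead viability series, textured bead phantoms, factorial
datasets) with exact ground truth, and every estimator is validated by
generate-then-recover tests against independent brute-force oracles.

## Worked example

Fit all four models to a noisy synthetic release curve whose truth is a
diffusion-dominant two-term law, pick the best and classify the
mechanism:

```r
library(probead)

truth <- kinetic_truth("peppas_sahlin",
                       list(k1 = 0.0806, k2 = -0.0023, m = 0.43),
                       noise_sd = 0.02, seed = 11)
curve <- simulate_release_curve(truth)   # 15-point digestion schedule
fits  <- fit_release_models(curve)
select_model(fits)
#> <model_fit> peppas_sahlin
#>   params: k1 = 0.0821774, k2 = -0.00261157, m = 0.43
#>   R2 = 0.992148 on 15 points
ps_contributions(fits$peppas_sahlin)
#> <mechanism_call> ps_dominance: mainly_diffusion
#>   evidence: diffusion_integral = 154.337, relaxation_integral = -40.5096, rf_ratio_end = -0.3414
```

The selected model recovers the generating coefficients (k₁ 0.082 vs
true 0.0806, k₂ −0.0026 vs −0.0023) and the negative relaxation term
marks release as diffusion-driven.

The full pipeline — simulate six bead scenarios with the two published
coefficient sign patterns, fit, classify, couple to growth, detect
equilibria, write JSON/CSV reports — runs from one seed:

```r
run_release_pipeline(seed = 42, out_dir = "report")
#> <digestion_report> 6 beads (seed 42)
#>   B     best = korsmeyer_peppas R2 = 0.993  mainly_relaxation  Da = 0.786  eq = 187 min
#>   AB    best = korsmeyer_peppas R2 = 0.994  mainly_relaxation  Da = 0.917  eq = 201 min
#>   WB    best = korsmeyer_peppas R2 = 0.996  mainly_relaxation  Da = 0.909  eq = 195 min
#>   AWB5  best = korsmeyer_peppas R2 = 0.991  mainly_relaxation  Da = 1.098  eq = 228 min
#>   AWB6  best = peppas_sahlin    R2 = 0.989  mainly_diffusion  Da = 2.292  eq = none
#>   AWB8  best = peppas_sahlin    R2 = 0.989  mainly_diffusion  Da = 1.306  eq = none
```

Control-type beads (relaxation sign pattern) release most of their cargo,
cross their in-bead viability curve during the intestinal phase and sit
at Da < 1 (transport-governed); the mixed agavin/whey scenarios release
less, never cross (the bead arrives intact) and have Da > 1
(reaction-governed cell trapping).

Morphometry and design optimization work the same way:

```r
ph <- simulate_bead_image(bead_phantom_spec(seed = 7))
shape_descriptors(binarize_threshold(ph$image, 70, 255))
glcm_features(ph$image, mask = ph$disc_mask)
boxcount_dimension(ph$network_mask)
gliding_box_lacunarity(ph$network_mask)

dat <- simulate_factorial_experiment(
  factorial_truth(list(area = c(5.4, 0.3, 0.8, -0.5, -0.2, 0.15))))
m <- fit_quadratic_surface(dat, "area")
optimize_composite(list(m), list(goal_from_surface(m, "maximize")))
```

See the vignette (`vignettes/bead-release-analysis.Rmd`) for the models,
defaults, numerical choices and limitations.

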