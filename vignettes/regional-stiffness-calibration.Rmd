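---
title: "Calibrating regional left-atrial stiffness with emulators, history matching and ensemble MCMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating regional left-atrial stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Passive left-atrial (LA) deformation during the ventricular systole — the
reservoir phase, when the closed mitral valve lets the chamber fill and
stretch — is shaped by myocardial stiffness, cavity pressure, the
pericardial constraint and the downward pull of the mitral annulus. Regional
stiffness cannot be measured directly in patients; it must be inferred by
matching a mechanical model to image-derived deformation. `lascal`
implements that inference chain end to end at desk scale: a reduced-order
five-region LA model stands in for a patient-specific finite-element
simulation, and the calibration machinery around it — Gaussian-process
emulation, Sobol sensitivity analysis, multi-wave history matching and
affine-invariant ensemble MCMC — follows the published protocol of the
full-scale study design it mirrors.

The package ships no clinical data. Everything it consumes is generated by
its own synthetic-study module, with known ground truth, so the whole
pipeline can be verified: parameters are drawn, observations are simulated
with a stated noise model, and the calibration is judged by whether it
recovers what generated the data.

## The forward model

The LA endocardium is split into five regions (anterior, posterior, septum,
lateral, roof). Each region `r` is an independent spherical thin membrane of
end-diastolic (ED) radius `R_ED_r` (mm), thickness `h_r` (mm) and area
fraction `a_r`, made of passive myocardium obeying the transversely
isotropic Guccione law

```
Psi = (C / 2) (exp(Q) - 1) + (kappa / 2) ln(J)^2
Q   = alpha (b_f E_ff^2 + 2 b_ft (E_fs^2 + E_fn^2)
             + b_t (E_ss^2 + E_nn^2 + 2 E_sn^2))
```

with reference exponents `b_f = 8`, `b_ft = 4`, `b_t = 3` and reference bulk
stiffness `C = 1.7` kPa (healthy-ventricle estimates), `kappa = 1000` kPa.
The single scaling `alpha` multiplies all three anisotropy exponents at
once; it is the per-region stiffness index the calibration targets, because
`C` and `alpha` are strongly correlated through `C (exp(alpha Q0) - 1)` and
cannot be identified jointly. Non-myocardial tissue (vein and appendage
rings, the annulus) is Neo-Hookean, `Psi = c (I1 - 3) + (kappa/2) ln^2 J`
with `c = 7.45` kPa for the rings; in the reduced model these structures are
not resolved and the law is carried for completeness of the constitutive
module.

On the membrane path the deformation is equibiaxial: in-plane stretch
`lambda`, through-thickness `lambda^-2`, `J = 1`, so the volumetric penalty
vanishes identically and the energy reduces to a scalar function
`W(lambda)`. Regional equilibrium under cavity pressure `p` balances the
membrane tension and the pericardial spring:

```
p[kPa] = (2 h / (R0 lambda^2)) dW/dlambda + k_peri w_r max(0, R0 lambda - R_ED) * 1000
```

`k_peri` (kPa/um) is the pericardial spring stiffness; the factor 1000
converts the radial excursion from mm to um; and the penalty weight
`w_r = clamp((psi_r - PTH) / (1 - PTH), 0, 1)` maps each region's roofness
coordinate `psi_r` through the threshold `PTH`, so the roof
(`psi = 1`) is always constrained, the near-annulus regions are free, and
the spring only ever resists outward motion beyond the imaged ED radius.
The single mmHg-to-kPa conversion (0.133322) lives at this interface and
nowhere else.

The load protocol is an idealised cycle on a 40-step unit-time grid:
a loading ramp 0 to EDP on [0, 0.2] (reloading the unloaded geometry),
a reservoir rise EDP to ESP on [0.2, 0.55], a conduit decline back to EDP on
[0.55, 0.85], then constant (no booster pump — atrial contraction is out of
scope). Mitral-annulus motion is a smooth `A sin^2` bump peaking (default
`A = 8` mm) at end-systole; each region feels it through a coupling weight
`c_r`, largest anterior and smallest on the roof. Regional displacement
combines the radial excursion with the annular pull,
`d_r = sqrt((R_r - R_ED_r)^2 + (c_r d_MV)^2)`, global displacement is the
area-weighted mean, and cavity volume is `(4 pi / 3) sum a_r R_r^3`.
End-systole is the volume-transient peak over the post-loading grid (ties to
the earliest index). The seven output features are end-systolic volume
(ml) and the global plus five regional displacements (mm) at that instant.

Because the imaged ED state is loaded, the stress-free reference is
recovered by backward-displacement unloading: iterate
`R0 <- R0 - omega (R_loaded(R0, EDP) - R_ED)` with an adaptive relaxation
`omega` until reloading reproduces the ED volume. The study-level
requirement is agreement within 1.0%; the solver's default tolerance is
much tighter (1e-4, then a bracketed per-region root solve if the iteration
stalls) so that the converged geometry varies smoothly with the inputs — a
loose stopping band would make every downstream feature discontinuous at
the scale of the band, which is poison for emulation. The equilibrium root
itself is isolated by bisection on `lambda` in [0.7, 3]; `dW/dlambda` uses
central differences with step 1e-6, cross-checked against the closed form in
the tests.

What the reduced model preserves from the full-scale study is the causal
structure of inputs to features: stiffer regions move less, higher ES
pressure fills more, the pericardium pins the roof, the annulus drags the
anterior and lateral walls. What it does not preserve is 3-D kinematics,
wall-thickness gradients within a region, vein anatomy, or contact with a
discretised pericardial sack. It is a surrogate with the same interface,
not a replica.

## Study conditions and the synthetic data

The calibration box follows the published exploration ranges: per region
`C` in [0.2, 6.8] kPa and `alpha` in [0.125, 4.0]; `EDP` in [1, 12] mmHg;
`ESP` in [13, 37] mmHg; `k_peri` in [1e-4, 5e-3] kPa/um; `PTH` in
[0.50, 0.95]. The 14-parameter mode varies all of these; after the
sensitivity analysis `C_region` is fixed at 1.7 kPa and the 9-parameter
mode calibrates the five alphas plus EDP, ESP, k_peri and PTH.

The verification truth sits near the centre of the box: alpha =
(2.12, 1.42, 2.57, 2.71, 2.78) for (anterior, posterior, septum, lateral,
roof), EDP = 4.50 mmHg, ESP = 29.6 mmHg, k_peri = 0.003 kPa/um,
PTH = 0.60. Observations add zero-mean Gaussian noise at two levels:
baseline (0.2 mm SD on each displacement, 5% on volume) and high (1.0 mm,
20%), the stated feature-tracking-aligned and worst-case uncertainties. In
the verification twin the volume SD is anchored to the noiseless simulated
ESV; for patient-style runs the convention anchors it to the ED volume —
both are recorded in the observation provenance.

Default anatomy is a 90 ml ED chamber with fixed ±5% regional radius
perturbations, thicknesses (2.0, 1.8, 2.5, 1.6, 2.2) mm, area fractions
(0.25, 0.25, 0.15, 0.15, 0.20), roofness (0.5, 0.7, 0.6, 0.4, 1.0) and
annulus coupling (0.8, 0.5, 0.6, 0.7, 0.1). Epicardial adipose tissue is a
per-region covariate only; it never enters the mechanics.

The cohort generator for the downstream statistics draws per-patient random
intercepts (`tau = 0.5` mm), per-region stiffness indices uniform on
[0.5, 4], and regional displacements from a linear model whose region
effects make the roof deform least (the robust qualitative feature of real
atria); thickness and fat are independent covariates with null coupling
unless configured otherwise. Passing tests on these data shows the
machinery is calibrated — not that real CT-derived cohorts share the
generator's linearity, Gaussian noise, or independence of anatomy from
stiffness.

## Emulation

Each of the seven features gets an independent Gaussian-process emulator:
a regression mean `h(x)' beta` plus a zero-mean GP with ARD
squared-exponential kernel on inputs normalised to the unit cube, fitted by
maximising the marginal likelihood (beta profiled by generalised least
squares; 5 restarts by default, L-BFGS-B on log scale). Training designs
are Sobol sequences with at least ten points per input dimension — 200
points for the 14-parameter box — with the sequence's origin point dropped,
the standard practice for unscrambled nets (it maps to the degenerate
all-minima corner of the box).

Four emulator choices matter and are deliberate:

* **Log-warped ratio-scale inputs.** C, alpha, k_peri and EDP span 12-50x
  ranges and the response is steep at their low ends; the kernel operates
  on log-transformed, then normalised, copies of these inputs.
* **Quadratic regression basis.** The mean function is linear in its
  coefficients with intercept, linear and squared terms (the published
  protocol states only "a linear regression model"; the basis is an open
  choice). Physics-informed extra regressors — each region's spring
  coefficient `k_peri w_r(psi_r, PTH)` and the log pressure ratio
  `log(ESP/EDP)` — encode the support-regime switch and the loading
  amplitude that the smooth kernel resolves poorly on its own.
* **Log output transform.** Features are positive with heavy right tails
  (soft, weakly supported corners balloon); the GP fits log(y) and reports
  lognormal moments on the feature scale.
* **Noise floor and variance calibration.** The jitter is floored at 1e-3
  of output variance (the scale of the simulator's numerical noise), and
  the predictive variance is rescaled by an internal five-fold calibration
  at the fitted hyperparameters, because plug-in maximum-likelihood
  variances are optimistic away from the training cloud. The calibration
  uses training data only.

Accuracy is reported by five-fold cross-validation: the coefficient of
determination R^2 = 1 - RSS/TSS on held-out points, and the independent
standard error ISE — the fraction of held-out points strictly within two
predictive standard deviations, the observed mass of the nominal ~96%
credibility band. Fold refits are warm-started from the full-data
hyperparameters. The acceptance bounds (every feature's mean R^2 at least
0.72 and mean ISE at least 0.89) reproduce the published minima.

## Sensitivity analysis and fixing C

Sobol indices are estimated with the Saltelli scheme: base matrices A and B
from a 2d-dimensional Sobol sequence plus both radial mixes, N(2d + 2)
evaluations of the emulator posterior mean; first-order indices use the
Saltelli 2010 estimator and total effects the Jansen estimator, both
averaged over the two directions. Inputs are ranked by their maximum total
effect across the seven outputs, normalised to sum to one. Emulator
uncertainty is not propagated into the indices — a documented limitation.
Within each region `alpha` outranks `C` (the two are confounded in
`C (exp(alpha Q) - 1)`), which justifies fixing `C = 1.7` kPa everywhere
and re-training 9-parameter emulators for calibration, as the protocol
prescribes.

## History matching

Calibration first shrinks the box by iterative implausibility screening.
For a test point x the implausibility is

```
I(x) = max_i |E[f_i(x)] - mu_i| / sqrt(Var[f_i(x)] + sigma_i^2)
```

over the seven features. A point is ruled out only if I strictly exceeds
the threshold; the schedule starts at 3.5 and steps down by 0.5 per wave to
the three-sigma floor of 3.0, where it stays. Each wave: fit emulators on
all simulations so far (200 in the first wave at full scale), score a
100 000-point Latin-hypercube test cloud, keep the non-implausible (NROY)
points, select a space-filling batch (greedy maximin, 100 points at full
scale) to simulate for the next wave, and refill the test cloud inside the
NROY region (fresh LHS candidates plus 5%-of-range Gaussian jitter around
retained points, filtered by the current emulators). The published protocol
never states the measure for "NROY reduction"; here it is the
non-implausible fraction of a fixed reference cloud drawn once over the
original box, which makes the stopping rule — a change below 1% between
waves — well defined. An emptied NROY set aborts with a model-data
incompatibility error rather than continuing.

## Posterior sampling

Over the final-wave NROY bounding box (the uniform prior), the posterior
combines the emulator-aware Gaussian likelihood — total variance
`sigma_i^2 + Var[f_i(x)]` per feature — with an affine-invariant ensemble
sampler: Goodman-Weare stretch moves with scale a = 2, updated in two
half-ensembles so whole blocks of proposals hit the emulators at once. The
full protocol is 18 walkers of 100 000 steps, burn-in 10 000, thinning 10;
desk-scale runs use 18 x 10 000 with burn-in 1 000. Walkers start at the
highest-likelihood NROY points (one per walker, lightly jittered): the
published protocol leaves initialisation unspecified, and starting the
whole ensemble in a small ball around a single point makes the stretch
move expand painfully slowly. Convergence is monitored by the integrated
autocorrelation time (ensemble-mean autocovariance, window c = 5) and
rank-normalised split-Rhat; if the autocorrelation time exceeds steps/50
the run doubles its step count, up to three times.

Reported outputs are the MAP (the stored sample of maximal log-posterior),
its nearest simulated design point in range-normalised Euclidean distance
(so a genuinely simulated parameter set accompanies the emulated optimum),
equal-tailed 95% credible intervals, and corner-plot contour levels at the
bivariate-Gaussian masses 1 - exp(-k^2/2) for k = 0.5, 1, 1.5, 2 — 11.8%,
39.3%, 67.5% and 86.4%.

## Verification and downstream statistics

`run_verification()` executes the whole chain on synthetic truth at both
noise levels and reports, per parameter: the 95% credible interval, whether
the truth lies inside it, and the MAP distance. The acceptance properties
are coverage at both levels and interval widening under the higher noise;
the published MAP distances themselves are properties of the full
finite-element model and are deliberately not acceptance values for the
reduced model.

The statistics module mirrors the study's downstream analysis. Regional
displacement is modelled as
`Y_ij = b0 + region effects + b2 X_ij + u_j + e_ij` with a random intercept
per patient, fitted by REML (lme4 is the engine; REML is that framework's
default and the protocol does not state the criterion). Coefficients are
tested by Wald z against the normal reference at the 0.05 level; covariates
enter in raw units by default (standardisation is a switch). Region pairs
are compared by paired t-tests with Bonferroni correction (raw p times 10
for five regions, capped at 1; a zero-variance difference yields p = 1 by
convention).

## Numerical choices, in one place

* Unloading: fixed-point update with adaptive relaxation; tolerance 1e-4
  on relative ED-volume error (study requirement 1%), cap 60 iterations,
  then a bracketed per-region root solve; near-zero EDP returns the ED
  geometry unchanged.
* Equilibrium: bisection on lambda in [0.7, 3], tolerance 1e-9; no sign
  change in the bracket is reported as non-physiological input, never
  clipped.
* Energy derivative: central differences, step 1e-6 in lambda.
* Time grid: 41 points on [0, 1]; t_load = 0.2, t_ES = 0.55,
  t_cond = 0.85 — the scale of 10-20 gated-CT frames plus a loading phase.
* Emulator optimisation: bounds delta in [0.03, 30] (normalised units),
  sigma_f^2 in [1e-3, 1e3], jitter in [1e-3, 1] of output variance; ES
  ties to the earliest grid index; degenerate extra-basis columns dropped
  by rank; duplicate training points absorbed by the jitter.
* Desk-scale budgets used by the test suite and acceptance script: 200
  training simulations (the full-scale number), history-matching test
  clouds of 15 000 points with a 120-simulation first wave and 60 per
  refill, MCMC at 18 x 10 000 with burn-in 1 000. The full-scale protocol
  (100 000-point clouds, 18 x 100 000 chains) is the package default in
  `default_config()` and `hm_config()`.

## Known limitations

The five-region spherical reduction cannot reproduce patient-specific
finite-element numbers; only structural and statistical properties
transfer. Sensitivity indices ignore emulator variance. The implausibility
measure takes the feature-wise maximum, so with seven features the
truth-retention probability under a threshold of 3 is slightly below the
single-feature three-sigma figure. The Gaussian likelihood treats
lognormal predictive moments as normal. Intermediate feature-tracking noise
levels between 0.2 and 1.0 mm are not modelled, matching the two stated
study conditions.
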