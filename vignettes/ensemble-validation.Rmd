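---
title: "Validating disordered-protein ensembles against SAXS and NMR observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating disordered-protein ensembles against SAXS and NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpval)
```

## The problem

Intrinsically disordered proteins (IDPs) do not fold into a single
structure: they sample broad conformational ensembles, and any simulated
ensemble is only as credible as its agreement with solution experiments.
`idpval` computes, from coordinate trajectories, the observables that
solution experiments actually measure — small-angle X-ray scattering
(SAXS) profiles, backbone ^15^N spin-relaxation parameters (T1, T2,
heteronuclear NOE), per-residue alpha-helicity, and backbone orientational
correlations — and scores simulation-versus-experiment agreement with a
transparent error-bar-overlap criterion.  A synthetic-data module supplies
inputs with closed-form ground truth (rotational diffusion on the sphere,
Gaussian chains, uniform spheres, ideal helices), so every stage of the
pipeline is testable without running molecular dynamics.

The package's worked reference system is a 91-residue plant LEA protein
studied as wild type and a G68A point mutant.  Because the actual mature
sequence is not redistributed here, the package ships
`cor15a_synthetic`: a **synthetic** 91-residue stand-in engineered once to
the documented statistics of that chain (length 91, Gly at position 68, a
polyampholyte composition with well-mixed charges, and formal net charge
-6 at pH 7.0).  All sequence-dependent machinery is generic.

## Global dimensions: R_G and scaling laws

The radius of gyration is the mass-weighted RMS distance of atoms from
the center of mass, reported per frame with median and quartiles (linear
interpolation between order statistics).  As external references the
package evaluates the polymer scaling law `R_G = R_G0 * N^nu` in two
parameterizations: denatured globular proteins (`R_G0 = 2` Å,
`nu = 0.598 ± 0.028`; the exponent uncertainty propagates into the
bounds) and folded globular proteins (`R_G0 = 3` Å, `nu = 1/3`, with
fixed +5.5/−2.0 Å bounds taken from the empirical width of the folded
distribution).  At `N = 91` these give about 29.7 Å and 13.5 Å — the
yardsticks between which a partly collapsed IDP ensemble should fall.

```{r scaling}
scaling_law_rg(91, "denatured")$value
scaling_law_rg(91, "folded")$value
```

## SAXS: Debye profiles, fitting, Guinier and Kratky analyses

Ensemble profiles are computed with the Debye formula over point atoms
with constant form factors equal to element electron counts,
`I(q) = sum_jk f_j f_k sin(q r_jk)/(q r_jk)`, averaged over frames.
**Deliberate deviation:** hydration-shell and excluded-volume
contributions (the envelope model of CRYSOL-type calculators) are *not*
modeled.  The package's profile generator is meant to be analytically
checkable (it reproduces the uniform-sphere form factor to a few
percent), and the downstream fitting machinery is independent of how the
profile was generated; profiles from an external calculator can be read
with `read_saxs_profile()`.  The default q grid has 76 points on
[0, 0.5] Å⁻¹ — the point count follows the reference workflow, the upper
bound is this package's choice since a maximum q is not prescribed.

Fitting to an experimental profile uses `I_fit = m * I_comp + n`
(amplitude `m` absorbs concentration/calibration, offset `n` absorbs
buffer-subtraction residuals), with weights `1/(eps_comp^2 + eps_exp^2)`.
Because the model is linear in `(m, n)`, the weighted normal equations
are solved in closed form; tests assert equivalence with an iterative
Levenberg–Marquardt solve to 1e-9.  The chi-square is reported exactly as
the weighted sum of squared deviations (no division by the point count) —
whether published chi-square values of this kind are reduced is generally
ambiguous, so `chi2_reduced = chi2/(n_pts - 2)` is always reported
alongside.  A flag (`use_eps_fit`) switches the denominator to
`eps_fit = m * eps_comp`, the variant under which chi-square is exactly
invariant to rescaling the computed profile.

Guinier analysis fits `ln I` against `q^2` inside the unfolded-protein
window `q R_G < 1.1`, iterating the window to self-consistency
(convergence at 0.1% change in R_G).  The Kratky transform `I q^2` is
provided for shape classification; note that for an ideal Gaussian chain
the plateau `2/R_G^2` is approached like `1/(q R_G)^2`, so the curve is
within 10% of the plateau only from `q R_G = sqrt(10) ≈ 3.2` on.

## NMR relaxation: C(t) → ILT → J(ω) → Redfield

For every backbone N–H bond vector the rank-2 orientational
autocorrelation `C(t) = <3/2 cos²θ − 1/2>` is averaged over all time
origins (computed via FFT on the six quadratic component products, so the
cost is `n log n`).  Prolines and the N-terminal residue carry no amide
proton and are skipped; the skip list is recorded in the output metadata.

`C(t)` is then decomposed into `N = 1000` exponentials with timescales
log-spaced on [0.1, 1e5] ps by a nonnegative, smoothness-regularized
least-squares fit (a regularized inverse Laplace transform): second
differences on the log-τ grid are penalized with a default `λ` chosen so
that `λ‖D‖² = 1e-3 ‖K‖²`, and nonnegativity is enforced with the
Lawson–Hanson active-set solver.  Lags beyond the first thousand are
thinned logarithmically so long lags do not dominate the residual.

**Statistical weighting.** Correlation functions estimated from finite
trajectories carry correlated noise in the decayed tail.  A nonnegative
fit can only *add* amplitude, so unweighted fitting rectifies that noise
into spurious slow-timescale weight, which inflates `J(0)` and biases T2
low by tens of percent — the single largest error source we found in this
pipeline.  When replicate trajectories are available, the lag-wise
scatter across replicates provides an error estimate, and
`fit_timescale_spectrum()` weights lags by its inverse (capped at a
50-fold ratio).  `relaxation_pipeline()` does this automatically with
three or more replicates, and `average_cf = TRUE` additionally fits the
replicate-averaged `C(t)` with SEM weights for the central values, which
is the most statistically efficient route for homogeneous replicates.
Error bars are always the SEM over per-replicate results.

The spectral density is evaluated in closed form,
`J(ω) = Σ α_i 2τ_i/(1 + (ωτ_i)²)` — the exact cosine transform of the
exponential decomposition; no quadrature is involved.  One normalization
subtlety deserves emphasis: with `C(0) = 1`, this `J` is five times the
conventional spectral density, so the bridge factor 1/5 is applied inside
`redfield_relaxation()` before the standard Redfield expressions for an
isolated ^15^N–^1^H pair with axial CSA.  This convention pair
(`C(0)=1` plus `J/5`) is pinned by an oracle test against the closed-form
Lorentzian limit at 1e-9 tolerance.  Constants default to the community
values `r_NH = 1.02` Å, `Δσ = −170` ppm, `γ_H = 2.6752218744e8`,
`γ_N = −2.7126e7` rad s⁻¹ T⁻¹, all overridable.  Field presets: `"600"`
uses the actual 597.427 MHz proton frequency of the 600 MHz instrument;
`"850"` uses a nominal 850.0 MHz because the actual frequency is not
documented.

A physical note: in the extreme-narrowing limit T1 = T2 holds for the
dipolar pathway, but CSA relaxation approaches `R2/R1 = 7/6` there, so
with the default constants T1/T2 ≈ 1.016 at very fast motion.  Tests of
the narrowing identity therefore set `Δσ = 0`.

```{r relax}
spec <- structure(list(tau = 5000, alpha = 1), class = "timescale_spectrum")
unlist(redfield_relaxation(spec, field_config("600")))[c("T1", "T2", "NOE")]
```

## Helicity and backbone correlations

Alpha-helicity uses the Kabsch–Sander electrostatic hydrogen-bond energy
`E = 0.084 * 332 * (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with the
−0.5 kcal/mol threshold; a residue is helical when it lies inside a run
formed by two consecutive i→i+4 bonds.  Only the alpha state is
assigned — 3₁₀, π and strand assignment are out of scope.  Missing amide
hydrogens are reconstructed 1.01 Å from N, anti-parallel to the preceding
C=O bond.  Helicity profiles average replicates with equal weight (with
equal-length replicates this is indistinguishable from frame-count
weighting).

The directional correlation map averages dot products of consecutive
Cα→Cα unit vectors over frames and replicates.  Rigid segments give
entries near ±1; independent orientations and consistently orthogonal
vectors both give 0, so the map flags *coupling*, not geometry.

## Agreement scorecard

For every observable the fraction of residues whose simulation and
experiment error bars overlap is computed with the combined error
`ε = sqrt(ε_exp² + ε_sim²)`; `|Δ| = ε` counts as overlap (the interval
still touches zero), with a tiny relative guard so exact boundary cases
survive floating-point representation.  Where no experimental error is
given the simulated bar alone is used.  For chemical shifts the combined
error is `sqrt(ε_sim² + ε_pred²)` with predictor uncertainties 0.49 ppm
(^1^H^N) and 2.45 ppm (^15^N); experimental shift errors deliberately do
not enter.  The scorecard's final row is the unweighted mean across
observables.

One caveat the scorecard inherits from its criterion: when both error
bars are honest 1-sigma statistical errors and deviations are purely
statistical, the expected overlap fraction is only ~0.68-0.76, not 1.
High fractions therefore occur where a dominant, generously quantified
error term exists (such as the shift-predictor uncertainty) or where
systematic agreement is genuinely better than the stated uncertainty
budget.  The package's closed-loop demonstration reflects this: its
prediction-error-dominated shift rows score near 1.0 while its
relaxation rows hover around the statistical expectation.

## Synthetic generators and what they do (not) show

* `simulate_rotdiff_vectors()` — Brownian rotation on the sphere with
  `D = 1/(6 τ_c)`; per-step angle `sqrt(4 D dt)|N(0,1)|` about a random
  perpendicular axis, renormalized every step (additive schemes drift).
  The small-angle regime is enforced by requiring `dt < τ_c/10`, keeping
  the `exp(−6 D t)` law exact to `O(dt²)`.
* `simulate_lipari_szabo()` — global tumbling composed with
  wobble-in-a-cone; the cone half-angle derives from
  `S² = [cos θ0 (1 + cos θ0)/2]²`, with reflection at the cone boundary
  applied inside the walk.
* `sample_gaussian_chain()` / `sample_sphere_beads()` — freely jointed
  chains and uniform balls with closed-form `⟨R_G²⟩`; unit masses, so
  mass-weighting is exercised separately with heterogeneous masses.
* `build_ideal_helix()` — N/H/Cα/C/O backbone from standard internal
  coordinates at φ = −57°, ψ = −47° (≈1.5 Å rise per residue, i→i+4
  O···H ≈ 2.1 Å).
* `make_noisy_table()` — Gaussian noise with the generating σ recorded,
  so error-weighted fits see exact weights.

These generators validate the *transfer functions* of the pipeline —
geometry in, observable out — under known dynamics.  They do not emulate
force-field-specific conformational statistics, solvent effects,
anisotropic tumbling, chemical exchange, or the correlated
internal-plus-global motions of real proteins; passing tests on them
shows the math is right, not that any particular simulation is.

## Numerical choices and problem sizes

* ILT grid 1000 points on [0.1, 1e5] ps; active-set NNLS on the
  Tikhonov-augmented system; lag thinning to ≤1000 log-spaced lags.
* The oracle recovery study uses isotropic tumbling at τ_c ∈ {1, 5, 10} ns,
  ten replicate trajectories of 1e6 steps at 1 ps — the replicate
  structure mirrors the n = 10 repeats over which experimental-style SEMs
  are defined.  Recovery of T1, T2 and NOE is within 3% of the
  closed-form Lorentzian values at both field presets.  At τ_c = 10 ns a
  1e6-ps trajectory spans only 100 correlation times, so the achievable
  statistical precision of a ten-replicate estimate is itself ~2%;
  the criterion sits close to the information-theoretic limit of these
  trajectory lengths.
* SAXS oracle fixtures: 2000 beads, 32 conformers.  Two sampling effects
  matter when comparing bead ensembles with the continuous sphere form
  factor near `q R = 4` (where P(q) ≈ 0.008): the incoherent self-term
  floor `(1 − P)/N` of discrete beads (+6.6% of P at N = 2000), removed
  by the cross-term (self-term-excluded) normalization, which is the
  unbiased estimator of P(q); and Monte-Carlo noise, controlled by the
  conformer count.  The physical profiles returned by `debye_profile()`
  keep their self terms — only the continuous-oracle comparison excludes
  them.
* Degenerate inputs: superposition requires ≥3 non-collinear atoms;
  Guinier windows need ≥3 points and positive intensities; single
  replicates report SEM = 0 with a warning rather than NA.

## Known limitations

Point-atom form factors without q-dependence; no hydration layer; only
the alpha-helix DSSP state; fixed intrinsic pKa values (no
structure-based shifts); isotropic overall tumbling assumed in the
synthetic oracles; no exchange contribution to T2; shift *prediction* is
consumed from external tools, never computed.
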