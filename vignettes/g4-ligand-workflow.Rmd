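---
title: "Quantifying G-quadruplex–ligand binding from native MS, ion mobility and optical data"
author: "G4LigandMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying G-quadruplex-ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(G4LigandMS)
```

# Scope and assumptions

G4LigandMS implements the quantitative workflow for characterizing the
binding of small ligands (quinoline/pyridine oligoamide foldamers in the
motivating application) to DNA G-quadruplexes by native electrospray mass
spectrometry, supported by drift-tube ion mobility, circular dichroism and
UV-melting. The package's working assumptions are:

* **Sequential two-site binding.** The target M binds up to two ligands:
  M + L ⇌ ML (KD1) and ML + L ⇌ ML2 (KD2). Higher stoichiometries
  (occasionally seen with short ligands and polythymine controls) are
  reported as observations, not fitted.
* **Equal response across adducts and charge states.** Intensities of one
  stoichiometry are summed over the full K⁺/NH₄⁺ adduct ladder and all
  monitored charge states before Eq.-5-style conversion; the electrospray
  response is assumed equal within a stoichiometry. Between
  stoichiometries, response factors are fixed at 1 for single-point
  screening and fitted freely in titrations.
* **Negative-mode adduct bookkeeping.** A K⁺ or NH₄⁺ adduct replaces one
  backbone proton (mass shifts +37.9559 and +17.0265 Da); each charge
  removes one proton. Average masses center the integration windows, since
  the 6–8 kDa envelopes at z = 4–6 are not isotope-resolved.

# Species quantification and screening

`speciesWindows()` places one window per (stoichiometry, K⁺, NH₄⁺, charge)
combination at the computed m/z; the default half-width is 1.0 Th scaled by
4/z. Integration is trapezoidal; three times the per-point noise standard
deviation (times √n for an n-point window) is subtracted from every
integral and clamped at zero — the same correction applied to screening and
titration data. Windows of different stoichiometry whose edges approach
within a tolerance are excluded deterministically and logged, rather than
split: splitting would require peak-shape models the data do not constrain.

`concentrationsFromIntensities()` then distributes the total DNA
concentration over M, ML, ML2 in proportion to their summed intensities;
free ligand follows by difference, and `kdSinglePoint()` evaluates KD1 and
KD2. The screening heatmap readout is the fraction of bound DNA.

**Censoring.** A single-concentration screen cannot distinguish very weak
binding from none: an unobserved species produces a one-sided bound
(e.g. "KD1 > [M][L]/floor" with a configurable detection-floor
pseudo-concentration, 0.01 µM by default), never a point value. A
non-positive free-ligand difference (possible with noisy intensities)
censors the result rather than producing a negative constant.

**Cooperativity.** For two identical independent sites with microscopic
constant kd, the 1:1 complex exists in two configurations, so KD1 = kd/2
and KD2 = 2kd: the non-cooperative expectation is KD2 = 4·KD1 exactly.
The classifier applies a relative tolerance band of 1e−6 around that
boundary (the defining convention uses only strict inequalities); the band
width is configurable and only matters for exactly-boundary inputs.

# The equilibrium solver

`solveEquilibrium()` is the forward model: for totals (M0, L0) and
constants (KD1, KD2), bound ligand is strictly monotone in free L, so the
state is found by bracketed root finding on free L over [0, L0]
(`uniroot`, absolute tolerance 1e−14·L0). The ligand mass balance is then
enforced exactly by recomputing free L from the complexes, which keeps both
balances at relative 1e−9 or better; the residual KD error stays below the
1e−6 round-trip tolerance asserted in the test suite.

# Titration fitting

The titration fitter replaces the single-point estimate with a weighted
least-squares fit of the full series (seven points, 0–40 µM ligand at
10 µM DNA, in the reference protocol):

* **Observable.** Each point's species intensities are normalized by their
  sum, removing the unknown per-point spray efficiency. The dT6 internal
  standard enters separately, through `responseDrift()`: the total-DNA to
  standard intensity ratio is regressed against ligand concentration
  (linear by default, constant optionally) and each point is renormalized
  to the zero-ligand ratio before fitting. A drifting ratio indicates
  ligand-dependent DNA response (e.g. charge-reduction-driven aggregation).
* **Parameters.** log KD1, log KD2, log r_ML, log r_ML2, bounded in
  [1e−4, 1e4] µM and [0.01, 100] respectively; r_M ≡ 1. The
  log-parameterization makes the bounds multiplicative and the local
  quadratic standard errors relative.
* **Weights.** Poisson-like, σ ∝ √I with a floor at three times the table
  noise sigma, reflecting counting detection; an equal-weights option
  exists since the reference software's weighting is not documented.
* **Initialization.** KD1/KD2 from the single-point estimator at the
  mid-titration point, responses at 1. With noise-free equal-response data
  this initialization is already exact, and the optimizer (L-BFGS-B plus a
  Nelder–Mead polish) keeps the refit within numerical precision — the
  basis of the 1% recovery checks in the tests.
* **Censoring.** A series with no detectable complex anywhere returns a
  censored-above fit rather than a boundary estimate.

# Ion mobility and CCS

`fitSteppedField()` regresses apex arrival times (parabolic interpolation
over the three points around the maximum — sub-bin precision without a
peak-shape model) against (L²·p·T0)/(p0·T)·1/ΔV; the slope is 1/K0 and the
intercept the dead time. `masonSchamp()` converts K0 to a collision cross
section with helium as drift gas.

**Reference-state constants.** The registry evaluates the Loschmidt number
density at T0 = 273.15 K and p0 = 760 Torr (the standard convention; a
275.15 K value occasionally appears in methods write-ups and is treated as
a typo). T0 and p0 remain overridable arguments everywhere they enter, and
the validations are round trips (synthesize → analyze → reconvert) that
are insensitive to the choice. The external calibrant is the tetramolecular
(dTG4T)4·(NH4)3 assembly with reference CCS 787.5 Å² (5−) and 735.7 Å²
(4−); `validateCalibrant()` applies the asymmetric 2% acceptance rule
|measured − reference|/reference ≤ 0.02.

`ccsDistribution()` transforms a full arrival-time distribution point-wise.
Because CCS is linear in (tA − t0) at fixed voltage, the transform is
strictly monotone (mode count preserved) with a constant Jacobian, applied
to the abundance so integrated area is conserved. Points at or below the
dead time are dropped with a warning.

# Potassium adducts and G-quartet counting

Structural K⁺ ions sit between stacked G-quartets with well-defined
stoichiometry; electrospray also attaches nonspecific K⁺ approximately
Poisson-distributed over the adduct number. `callSpecific()` calls adduct
n specific when (i) its intensity exceeds 1.5× both the n−1 and n+1
channels and (ii) it exceeds the fitted Poisson background by more than
three background standard deviations. The defining criterion is qualitative
("significantly more populated"); both thresholds are configurable and
reported in the output. Design notes:

* The background (`fitPoissonBackground()`) is a conditional
  maximum-likelihood Poisson fit with candidate channels — interior local
  maxima — treated as missing, so a specific spike does not inflate the
  background mean.
* The "three sigma" scale is the residual standard deviation of the masked
  background fit. Using √(predicted counts) instead would break the
  invariance of the call under rescaling of the profile, which must hold
  because profile units are arbitrary.
* n = 0 is never a candidate: zero adducts is not a structural site, and a
  monotonically decaying ladder must yield no call.
* n specific K⁺ imply n + 1 quartets; with several specific channels
  (topology mixtures) all are reported and the maximum sets the quartet
  count.

# Optical curves

CD spectra convert to molar ellipticity, Δε = θ/(32980·c·l). Melting
curves at 295 nm (G4) or 260 nm (duplex) are corrected by the 335 nm
internal reference channel (additive drift), then converted to folded
fraction θ(T) = (L0(T) − A(T))/(L0(T) − L1(T)) with affine baselines. T_M
is the first θ = 0.5 crossing in the ramp direction, linearly interpolated;
multiple crossings are flagged (multiphasic melts, seen for some
ligand complexes, are detected but deliberately not decomposed — how to
assign two transition temperatures is not constrained by the data model
here). θ values outside [0, 1] from noise are preserved, not clipped.

**Baseline identifiability.** The default windows are the lowest and
highest 15% of the temperature span, with which-side-is-folded decided by
the wavelength's sign convention (295 nm: folded absorbs higher). Window
baselines are, however, biased whenever a transition tail reaches into a
window — extrapolating ~20 °C across the transition amplifies sub-percent
tail contamination into several tenths of a degree in T_M. The package
therefore provides `refineBaselinesTwoState()`: a global fit of
A(T) = L0(T)(1−θ) + L1(T)θ with a two-state sigmoid θ, initialized from
the window estimates, whose *baselines* are returned. The folded-fraction
conversion and the 0.5-crossing definition of T_M are unchanged, and the
sigmoid's shape parameters are internal (van't Hoff enthalpy extraction is
intentionally out of scope). The refinement falls back to the window
estimates, with a warning, when the global fit does not improve —
typically on multiphasic curves. The `melt` pipeline uses the refinement;
the plain window fit remains the primitive and is accurate when both
flanks are fully developed (transition at least ~20 °C from both scan
edges for enthalpies near 200–250 kJ/mol).

# The synthetic world

The generators in `simConfig()` state the conditions every analysis stage
assumes; their defaults are fixed, not tuned:

* Screening: 10 µM DNA, 20 µM ligand, 4 µM dT6; titration grid 0, 5, 10,
  15, 20, 30, 40 µM — the reference experimental design.
* Stepped field: 8 voltages from 400 to 1500 V, 78.1 cm tube, 3.95 Torr,
  296 K, 0.3 ms dead time.
* Adducts: specific K⁺ counts (1 for free DNA, 2 for complexes — a 2- vs
  3-quartet contrast) convolved with a Poisson background, λ = 0.8 by
  default (ladders of ~5 visible adducts). Smaller λ (~0.3) reproduces the
  sparse ladders where the specific adduct clearly dominates both
  neighbours.
* Spectra: Gaussian peaks of σ = 0.25 Th on a 0.02 Th grid, charge states
  4–6 weighted 0.3/0.5/0.2, 1000 intensity units per µM, additive Gaussian
  noise. Titration tables use multiplicative log-normal noise (spray
  fluctuation regime) and can inject a linear response drift.
* Melting: two-state van't Hoff curves, default T_m = 55 °C and unfolding
  enthalpy 200 kJ/mol (typical of intramolecular G4s in dilute K⁺), with
  the folded 295 nm baseline above the unfolded one.
* CD: fixed Gaussian band fixtures for parallel / antiparallel / hybrid
  signatures — band positions are conventions for testing the conversion
  arithmetic, not fitted science, and are documented as such.

What a green test does **not** establish: the generators produce idealized
Gaussian peaks without isotope fine structure, detector saturation, spray
instability beyond the injected drift model, or chemical noise; real
spectra additionally require the analyst to confirm window placement
against the observed envelopes. Recovery tolerances in the test suite
(e.g. 2% relative abundance at SNR ≥ 50, 15% median KD1 at 5%
multiplicative noise) are statements about this stated world.

# Numerical choices

* Mass arithmetic from elemental composition (5′-OH/3′-OH strands:
  nucleosides plus HPO3 − H2O per phosphodiester bridge); proton mass
  1.007276 Da, helium 4.0026 Da, all constants in `msConstants()`.
* Equilibrium root finding is bracketed and monotone — no convergence
  failures are possible for positive inputs; the solver still verifies its
  residual and aborts loudly rather than returning a bad state.
* The titration objective is smooth in log-parameters; the L-BFGS-B /
  Nelder–Mead pair guards against the flat valley that appears when KD2 is
  much larger than the probed concentration range (then only a KD2 lower
  bound is effectively identified and its standard error is large — the
  reported uncertainty carries that information).
* mzML support is a deliberate minimal subset (uncompressed 64-bit
  little-endian arrays) sufficient for lossless round trips of synthetic
  spectra; vendor files should be exported to two-column tables.

# Known limitations

* Two binding sites at most; no competition or kinetic models.
* No charge-state deconvolution or isotope-resolved fitting; overlapping
  windows are excluded, not decomposed.
* Multiphasic melting curves yield a flagged first crossing only.
* Mixed Na⁺/K⁺ adduct ladders are not deconvolved.
* The adduct significance thresholds (1.5× neighbours, 3σ background) are
  declared conventions; they are reported in every call and should be held
  fixed within a study.
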