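---
title: "Methods: fast-water construction and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fast-water construction and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastwater)
```

This vignette documents the models, estimators and numerical choices behind
`fastwater`. Units are fixed package-wide to GROMACS conventions: g/mol,
nm, ps (ns for transport and relaxation times), fs for integration time
steps, kJ/mol, K, with k~B~ = 0.0083144621 kJ/(mol·K).

## 1. Mass model

Classical equilibrium averages depend on the potential only, not on
particle masses: the configurational Boltzmann weight exp(−U/k~B~T)
carries no mass. Scaling all solvent masses by f² is therefore exactly
equivalent to rescaling time by f in the solvent dynamics — viscosity
η′ = f·η, self-diffusion D′ = D/f, relaxation times τ′ = f·τ — while every
structural and thermodynamic observable is untouched. `fastwater` builds
"fast" 3-site water variants in two exact steps:

1. **Repartition** mass m~r~ from the oxygen to the two hydrogens
   symmetrically (m~O~ − m~r~, m~H~ + m~r~/2). This slows the fastest
   librational motions and stabilizes integration, at fixed total mass.
2. **Rescale** all site masses by m~tot~/M₀ so the molecular mass becomes
   m~tot~.

`repartition_and_rescale()` keeps full precision; the returned masses sum
to the target total to 1×10⁻⁹ relative. The two steps commute with a
subsequent rescale (composition law), which the tests exercise over random
specs.

**Reporting convention.** For publication-style 3-decimal tables and for
topology files, `round_masses()` rounds the hydrogen mass and quotes the
oxygen mass as the remainder m~tot~ − 2·m~H~′, so the printed site masses
sum exactly to the molecular mass. Rounding each site independently can
lose 0.001 g/mol of total mass (for m~r~ = 4, m~tot~ = 1.116 the
full-precision oxygen mass is 0.743327, which rounds to 0.743 even though
the consistent table value is 0.744); a topology whose masses do not sum
to the intended molecular mass silently changes the model, so the
total-preserving convention is used everywhere masses are quoted.

**Time–mass equivalence.** `equivalent_time_step(dt, m_tot, m_ref)`
returns dt·√(m~ref~/m~tot~): a 2 fs simulation of water at m~tot~ between
1.5 and 0.5 g/mol probes effective steps between 7 and 12 fs.
`mass_for_time_step(m_tot, r)` inverts it: doubling the step requires
quadrupling the mass to keep per-step displacements — and hence the crash
rate — fixed.

**Topology editing.** `apply_to_topology()` edits only the mass column of
the matching 3-atom `[moleculetype]`; every other byte (spacing, comments,
other sections) is preserved and the operation is idempotent. Atom roles
are positional (atom 1 = O), matching the conventional ordering of rigid
water blocks; element names are not parsed. Only the GROMACS TOP/ITP
dialect and 3-site waters are supported — the algebra above is specific to
one heavy atom with two symmetric hydrogens, and 4-site/virtual-site
models would need their own treatment.

## 2. Crash kinetics

Integration failures are modelled as a Poisson process: exponential
waiting times with rate k~crash~. A replica either crashes at t
(event) or ends intact at t (censored observation); both contribute time
at risk. The maximum-likelihood estimator is

k̂ = n~crash~ / Σᵢ tᵢ,

with the Cramér–Rao standard error k̂/√n~crash~. Design choices:

* **Zero crashes.** The MLE is 0 and the SE is undefined at the boundary;
  `estimate_crash_rate()` reports a one-sided upper 95% bound
  ln(20)/Σtᵢ instead (the rate at which zero events in Σtᵢ has
  probability 0.05).
* **Normalization.** With `n_molecules` given, rates are quoted per
  (ns × 1000 molecules), the natural unit for comparing systems of
  different size.
* **Mass dependence.** At fixed repartitioning and time step the rate
  falls approximately exponentially in the total mass,
  k = A·exp(−c·m~tot~). `fit_exp_mass_model()` fits this as a weighted
  straight line in log space (σ~ln k~ = se/k̂ = 1/√n~crash~), which is
  stable across the many decades such data span; zero-rate points carry no
  log-space information and are dropped with a warning. Because the
  weights are absolute (Cramér–Rao) variances, the parameter covariance is
  (XᵀWX)⁻¹ without a residual-variance factor. `iso_crash_mass()` inverts
  the fit at a target rate; a family of fits over m~r~ traces an
  iso-stability contour, on which the fastest-diffusing stable model can
  be chosen. The microscopic crash mechanism itself (critical
  displacements, rotational effects) is deliberately out of scope; only
  the exponential approximation is implemented, and it is validated on
  synthetic data.

## 3. Trajectory kinetics

**Unwrapping.** Under a barostat the box fluctuates and coordinates are
rescaled with it, so the naive displacement accumulation
u~k~ = u~k−1~ + Δw − L~k~·round(Δw/L~k~) accumulates a systematic error
proportional to (image index)·ΔL. `unwrap_npt()` therefore selects, per
axis, the periodic image of the wrapped coordinate closest to the previous
unwrapped position scaled by the box ratio:

u~k~ = w~k~ − L~k~·round((w~k~ − (L~k~/L~k−1~)·u~k−1~)/L~k~).

For a constant box this reduces to the familiar minimum-image scheme; for
fluctuating boxes it is exact whenever true frame-to-frame displacements
stay below half a box edge, which the tests verify to machine precision
against the Brownian generator's retained ground truth. Reconstructed
jumps above 45% of a box edge trigger an aliasing warning (the frame
spacing is then too sparse for unambiguous unwrapping). Only orthorhombic
boxes are supported.

**MSD and the GLS fit.** `msd()` averages squared 3D displacements over
all overlapping time origins and particles (FFT decomposition, O(N log N)
per signal). Overlapping origins make neighbouring MSD points strongly
correlated, so an ordinary least-squares line through them badly misstates
its own uncertainty. `fit_diffusion()` fits MSD(τ) = 2·dim·D·τ + b by
generalized least squares using the exact covariance of the MSD estimator
for independent Gaussian walkers. For lags n ≤ m (in steps, N steps
total), writing g(d) = max(0, min(n, n−d, m+d)) for the overlap of two
displacement windows offset by d and c(d) for the number of origin pairs
at that offset,

cov(msd~n~, msd~m~) = 2σ⁴ Σ~d~ c(d)·g(d)² / ((N−n+1)(N−m+1)),

per 1D signal with step variance σ²; the dim-summed, particle-averaged
curve has covariance dim·cov/P. The unknown σ² = 2DΔt is taken from an
initial OLS slope and refined once. The quality factor Q is the
upper-tail χ² probability of the GLS residual (dof = lags − 2): uniform
on [0, 1] when the diffusive model and covariance hold, so a mean near 0.5
over repeated experiments is itself a calibration check, which the
acceptance battery performs. Defaults: shortest lag t~min~ = 20 ps
(excludes short-lag artefacts in MD data; at desk scale it simply removes
the most model-sensitive points), at most 40 evenly subsampled lags
(overlapping lags beyond that are almost fully redundant), dim = 3 (a 2D
option covers membrane diffusion). If the covariance is numerically
ill-conditioned the fit falls back to OLS with particle-bootstrap errors
and a variance-weighted χ²; the `method` field records which path ran.

**Finite-size extrapolation.** Periodic self-interaction depresses
diffusion as D(L) = D~∞~ − k~B~Tξ/(6πηL), ξ = 2.837297 for a cubic box.
`finite_size_extrapolation()` fits D against 1/L; the intercept is D~∞~
and the slope yields the shear viscosity η = k~B~Tξ/(6π|slope|), reported
in Pa·s. A non-negative slope flags η = ∞ (no resolvable finite-size
effect). `yeh_hummer_prediction()` is the exact inverse, used for
round-trip validation to 1×10⁻⁹.

**Equipartition diagnostics.** `rigid_body_temperatures()` decomposes
site velocities of 3-site molecules into centre-of-mass translation and
rigid-body rotation (ω = I⁻¹L about the COM; rotational energy ω·L/2 over
3 degrees of freedom) and reports T~trs~ and T~rot~. In mass-weighted
velocity space the translation/rotation/vibration split is orthogonal, so
Maxwell–Boltzmann site velocities give T~trs~ = T~rot~ = T in expectation
— the basis of the sampling oracle in `sample_water_velocities()`.
Diverging temperatures diagnose integrator artefacts that grow with the
effective time step. Collinear site geometries make the inertia tensor
singular and raise an error.

## 4. Sampling efficiency

**ACFs.** `autocorrelation()` is the mean-subtracted, variance-normalized
ACF with unbiased per-lag normalization (ρ₀ = 1 exactly). For circular
variables `vdsb_dihedral_acf()` computes C(t) = ⟨cos(θ(t₀+t) − θ(t₀))⟩,
which needs no mean subtraction but decays to a plateau near the order
parameter S~D~² for a confined dihedral; `normalize = "plateau"` rescales
to (C − S²)/(1 − S²) so that integrated times measure the decay rather
than the plateau. The CLI `act` command uses the plateau-normalized form
for circular input for exactly this reason.

**Order parameter.** S~D~² is defined here as the squared circular
resultant ⟨cos θ⟩² + ⟨sin θ⟩², the standard circular concentration
measure: 1 for a delta distribution, 0 for uniform or symmetrically
cancelling distributions. Other definitions exist in the dihedral-order
literature; this one is stated prominently because downstream numbers
depend on it.

**τ~int~.** frame_dt·(1/2 + Σ₁^W ρ~k~), with the truncation window W from
the Sokal automatic rule — the smallest W ≥ c·τ~int~(W) (c = 5 by
default), balancing truncation bias against the O(W/n) variance of the
tail sum — or, alternatively, the first negative ACF value. With several
replicas the SE is the across-replica standard deviation over √n; this is
an honest, assumption-free error estimate, whereas single-series ACT error
formulas depend on the very windowing being tested.

**τ~exp~.** A least-squares line through ln C(t) over a user-given range,
or automatically over the lags where C ∈ [0.05, 0.5] — late enough that
fast initial processes have died away, early enough that log-noise has not
taken over. Non-positive ACF values inside the range are an error, not
silently dropped.

**Block averaging.** `block_sem()` doubles block sizes while at least 16
blocks remain; the SEM of block means plateaus once blocks exceed the
correlation time. The plateau is detected as the first doubling that
changes the SEM by < 5%, and the plateau tail is averaged to reduce noise;
if no plateau is reached the largest-block value is returned with a
warning (the series is then too short for its correlation time).

**Free energies.** G~i~ = −k~B~T·ln p~i~ from equal-width histogram
counts, shifted so the lowest finite value is zero (the absolute offset of
a free energy is not an observable; min-shift makes profiles comparable).
Empty bins are masked as NA rather than set to 0 — a zero there would
fabricate a deep minimum. Defaults: 72 bins of 5° for dihedrals,
Freedman–Diaconis for distances. The 2D version supports difference maps
on shared bins, with an error if the grids differ. Two profiles from
independent runs of the same system agree within k~B~T wherever bins hold
enough *independent* samples (≈ counts/2τ~int~ ≥ 10); the largest
deviations live at the sparsely-visited distribution edges, and the tests
assert both sides of that statement.

**Replica KS comparison.** Correlated MD samples break the nominal KS
null distribution, so no p-values are computed from it. Instead
`ks_replica_comparison()` builds the empirical distribution of the
two-sample KS statistic itself: all unordered within-group pairs and all
cross pairs (no subsampling). The overlap summary — the fraction of
between-group statistics below the 95th percentile of the pooled
within-group values — is ≈ 1 when both groups sample the same
distribution and collapses toward 0 under a shift of a few standard
deviations. Tie groups are resolved before the maximum ECDF distance is
taken, so a replica compared with itself gives exactly 0; the statistic
matches `stats::ks.test` to machine precision (cross-checked in the
tests).

**Internal friction.** `internal_friction_fit()` fits τ = a + b·√m~tot~
(weighted when SEs are given, with the (XᵀWX)⁻¹ covariance of known-error
regression). The intercept a is the relaxation time that survives as the
solvent mass — hence viscosity — is extrapolated to zero: the practical
ceiling on solvent-mass speed-ups.

## 5. Synthetic generators: what they emulate, and what they do not

All generators take explicit seeds and are bit-reproducible.

* `simulate_crash_records()` draws exponential waiting times censored at
  t~end~ — exactly the stability model above, with no rotational or
  system-size effects.
* `generate_brownian_system()`: independent Gaussian walkers (per-axis
  step variance 2DΔt) wrapped into a cubic box whose edge follows a
  bounded AR(1) process (stationary relative sd `box_fluct_rel`, default
  0.003 — the typical sub-percent volume fluctuation of an NPT water box —
  AR coefficient 0.95, clipped at 3 sd so the box stays positive). The
  true continuous path is retained as ground truth. It emulates what the
  unwrapping and MSD/GLS contracts need — free diffusion under a
  fluctuating periodic box — and nothing else: no hydrodynamic
  correlations between particles, no barostat coupling of particle
  positions to the box, no velocity correlations at short lags, no
  finite-size depression of D. Passing tests therefore certify the
  estimator chain, not the physics of any particular water model.
* `generate_dihedral_series()`: Euler–Maruyama integration of overdamped
  Langevin dynamics on U(θ) = Σ k~j~ cos(jθ − δ~j~), with effective
  friction γ~eff~ = γ~floor~ + γ·√(mass_scale). Its stationary density
  exp(−U/k~B~T) is friction-independent — the generator-level embodiment
  of mass-invariant equilibria — while relaxation times scale as √mass;
  the additive floor mimics the residual internal/thermostat friction that
  produces a nonzero intercept in τ vs √m. Steps with
  dt > 0.5·γ~eff~/max|U''| are refused (Euler–Maruyama becomes unstable
  near that bound; max|U''| is bounded by Σ|k~j~|j²). Initial angles are
  drawn from the stationary density by inverse-CDF sampling, so no burn-in
  is discarded. It does not emulate inertial (underdamped) dynamics, the
  Kramers low-friction turnover, multidimensional coupling between
  dihedrals, or explicit solvent.

## 6. Problem sizes and statistical tolerances in the test suite

Test scales were chosen so each statistical assertion sits several
standard errors away from its threshold under the null: crash-MLE
calibration over 1000 synthetic datasets (k = 0.1 ns⁻¹, 40 replicas of
5 ns); the diffusion pipeline over 200 seeds of 100 particles × 5000
frames at D = 23.65 nm²/ns (per-seed 3·SE recovery and mean Q in
[0.4, 0.6]); dihedral mass-invariance at mass scales {1, ¼, 1/16} with
6 replicas × 2×10⁵ steps each (pairwise KS p > 0.01 on samples thinned to
~10× the slowest τ~int~; √m scaling of τ~int~ within 10%, which leaves
headroom over the few-percent Euler–Maruyama discretization bias);
equipartition at 10⁵ molecules (both temperatures within 1 K, ~1.3σ of
the Maxwell–Boltzmann sampling error); AR(1) τ~int~ at n = 10⁶ against
the closed form (1/2 + ρ/(1−ρ)) within 5%. Exact algebraic claims
(mass tables, Yeh–Hummer round trips, noiseless fits) are asserted to
1×10⁻⁹ or tighter.

## 7. Known limitations

* 3-site, orthorhombic, GROMACS-dialect only; no solute mass editing and
  no force-field parameter changes (charges and Lennard-Jones are never
  touched).
* The GLS covariance assumes free diffusion of independent walkers. On
  real MD data, interactions and hydrodynamics perturb it; Q then drifts
  from uniformity even when D is accurate, and the 20 ps minimum lag is
  doing real work.
* The exponential crash-rate law is an approximation that holds at fixed
  m~r~ and time step; extrapolating a fitted contour far outside the
  fitted mass range inherits that approximation.
* Equipartition diagnostics assume rigid 3-site geometry; flexible waters
  mix vibrational energy into the residual velocities.
* The KS overlap summary is a descriptive diagnostic, not a calibrated
  test; it answers "do between-group differences exceed replica-to-replica
  variability?" and nothing sharper.
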