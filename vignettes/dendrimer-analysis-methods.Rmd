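---
title: "Methods: dendrimer trajectory observables, electrostatics and NMR relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dendrimer trajectory observables, electrostatics and NMR relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendritraj)
```

This vignette records the models, conventions and numerical choices behind
`dendritraj`, in the spirit of a methods section: what each observable is,
which knobs matter, what the synthetic generators do and do not emulate, and
where a genuinely open design choice was settled.

## Scope and units

The package analyses trajectories of a single charged, roughly spherical
macromolecule (a peptide dendrimer is the motivating case) with explicit
counterions in a cubic periodic cell, salt-free. Units are fixed throughout:
nm for length, ps for trajectory time stamps, ns for correlation lags, amu
for mass, elementary charges for charge, kelvin for temperature. Converters
live only at the I/O boundary. Frames carry the cubic cell edge; before any
radial analysis the molecule is made whole by a breadth-first traversal of
its bond graph and unbonded species are wrapped to the periodic image
nearest the molecular centre of mass, because every radial observable is
defined relative to that centre. The wrap leaves atoms that need no image
shift bit-identical, so text round trips are exact.

## Conformational observables

`radius_of_gyration()` is mass-weighted; the gyration tensor in
`gyration_tensor_asphericity()` is deliberately *unweighted* (1/N), and the
two are kept separate because the shape parameter is conventionally defined
on bead positions while the size is a mass property. Asphericity runs from 0
(sphere) to 1 (line); collinear input is legal and returns exactly 1.

The Kirkwood estimate `Rh = 1/⟨1/r_ij⟩` is an O(N²) double sum over a
configurable selection (default: all non-counterion atoms, hydrogens
included — whether hydrogens belong in the sum is genuinely unsettled, so it
is an option, not a constant). Coincident atoms make the sum singular and
are a hard error naming the pair. Two limits anchor interpretation: a
Gaussian coil has Rh/Rg ≈ 0.67 and an impenetrable homogeneous sphere has
(Stokes radius)/Rg = √(5/3) ≈ 1.29. Note the second limit concerns the
*geometric* radius: the Kirkwood double sum itself on a uniformly filled
ball converges to 5R/6 (ratio ≈ 1.08), so the test suite asserts the
rigid-sphere limit through `rigid_sphere_radius()` (i.e. √(5/3)·Rg ≈ R on a
sampled ball), which is the physical content of the 1.29 ratio.

Size fluctuations are reported as observed max − min of the Rg series (with
the standard deviation alongside), and relative fluctuation as range/mean —
the min/max convention makes small-sample comparisons with visual traces
direct, which is why it is the primary statistic.

## Radial profiles and the effective charge

All profiles bin distance from the per-frame molecular centre of mass on a
uniform grid. Defaults: `dr = 0.02` nm for density and charge, `0.01` nm for
the ion-pair RDF — fine enough to resolve a ~0.3 nm contact peak with ≥10
bins while keeping per-bin statistics workable at a few hundred frames.
Density bins divide by the shell volume `4πr²dr`, so shell masses sum
exactly to the selected mass (a conservation identity the tests assert).

The ion-pair RDF uses minimum-image distances and the standard
ideal-mixture normalisation, so `g(r) → 1` far from contact; `r_max` beyond
half the cell edge is refused. Ion pairs are counted by integrating the
first peak: the default cutoff is the first local minimum of g(r) after its
first maximum (`first_peak_cutoff()`, fallback 0.4 nm when no interior
minimum exists). Counting is *exclusive* — each counterion is assigned to
its nearest cation within the cutoff and counted once, ties broken toward
the lower atom index — because the physical question is how many counterions
are condensed, not how many geometric pairs exist; the inclusive count is
returned as an attribute for comparison.

The net charge profile `q(r)` holds per-bin charge (positive solute charges
plus negative counterions), so its running sum is the cumulative charge
`Q(r)`; electroneutral input is required and the final bin of `Q` returns to
zero at machine precision. The effective charge `Q*` is the maximum of the
*raw* binned `Q(r)` and `R_max` its bin centre, ties toward smaller r — no
smoothing, trading aesthetics for exact reproducibility.

## Electrostatics

The dimensionless potential `ψ = eΨ/kBT` solves
`ψ'' + (2/r)ψ' = −4π λ_B ρ_q(r)` with `ψ(D) = 0` at the cell-equivalent
radius `D = √3·a_cell/2` and regularity at the origin. Because the module's
`q(r)` is a per-bin charge, the source density is reconstructed as
`q(r)/(4πr²dr)`; this convention is fixed by requiring that a thin charged
shell reproduce its analytic potential `λ_B Q (1/r − 1/D)`, which the test
suite checks to 1% at ≥500 bins for both solvers.

Two independent solvers are shipped. The reference is the Green's-function
quadrature `ψ(r) = λ_B [Q(r)/r + ∫_r^D q(x)/x dx]`, evaluated by direct
summation (exact for shell sources). The second route substitutes `u = rψ`,
which turns the operator into a plain 1-D Laplacian, and relaxes the
finite-difference equations by red–black successive over-relaxation until
`max|Δu| < 1e-9`. A damped fixed-point iteration on the integral form was
considered and rejected: for plain Poisson (no self-consistency between ψ
and the source) the integral form *is* the solution, so iterating it tests
nothing; SOR on the differential form is a genuinely independent numerical
route. The two agree to well under 0.5% on all fixtures.

The zeta potential is Ψ interpolated at exactly `R_max` — the radius where
the diffuse layer begins — in mV via `kBT/e`. Surface charge density is
`σ = Q*/(4πR_max²)`. Both are linear in `Q*` at fixed geometry, a property
the tests sweep.

The soft-sphere charge-renormalization relation
`Q* = (R/λ_B)(1/2ν)·ln[(Q/Q*−1)(D³/R³−1)]`, with `ν = 3/5` for dilute
solutions, is solved by a bracketing root finder on (0, Q) to
`|f(Q*)| < 1e-10`. The printed form of this relation is typographically
fragile in the literature; the implemented algebra is isolated in one
residual function (`soft_sphere_residual`) so an alternative reading is a
one-line change, and the residual provably changes sign exactly once on
(0, Q) — the dense-scan oracle in the tests confirms a unique root for every
parameter set exercised. The dielectric constant defaults to a fixed
ε = 80; a temperature-dependent ε(T) is the caller's choice via
`bjerrum_length(T, epsilon)`, since both conventions are in circulation.

`osmotic_ion_count()` is the bookkeeping identity
`n_osm = Q_bare − Q* − ⟨n_pairs⟩`; physically inconsistent (negative)
results warn but return, so pipelines can surface rather than mask the
inconsistency.

## Hydrogen bonds

A donor/hydrogen/acceptor triple is a bond iff the donor–acceptor distance
is < 0.35 nm *and* the angular criterion is < 30°, both strict — geometries
exactly at a boundary are excluded. The angular convention is genuinely
ambiguous in common prose ("angle between the donor and acceptor bonds");
the default is the donor-centred convention ∠(D→H, D→A) < 30°, the most
widespread in MD analysis, with the linear convention (deviation of
D–H···A from 180°) available via
`hbond_criterion(convention = "linear")`. A hydrogen participates in at
most one bond per frame; among qualifying acceptors the closest wins, ties
broken by atom index, so counting is deterministic.

## Autocorrelation functions and relaxation times

All ACF estimators average over every time origin with per-lag
normalisation by `n − k`, computed via FFT (lagged product sums) and
truncated at half the record; the test suite pins the estimator to the
direct O(n²) double loop at 1e-12. The estimator choice (all origins,
`n − k` normalisation) is a documented default — it is the standard
variance/efficiency compromise — since several conventions exist. Order-2
ACFs expand `(u(0)·u(t))²` over the six unique component products, which
keeps the FFT route exact. The scalar ACF is variance-normalised so
`C(0) = 1` identically.

Relaxation times are read off at the first downward crossing of 1/e with
linear interpolation; only the first crossing counts because long-lag ACFs
are noisy and can re-cross. For rigid-body rotation `P2 = P1³`, so
`τ_rot = τ_P1/3` exactly.

## From ACF to NMR observables

The order-2 ACF is split at its first crossing of `P_cut` into a tabulated
head and an exponential tail `P_splice·exp(−(t−t_splice)/τ_tail)`, with
`τ_tail` from a least-squares fit of ln P₂ over the `n_approx` lags before
the crossing. The extension is anchored at the last tabulated value rather
than at `P_cut` itself: continuity at the splice is the only reading under
which the two-part function is well defined. Group-specific defaults follow
the CH₂ vector classes: `P_cut` 0.04/0.05/0.05/0.08 and `n_approx`
100/100/100/1000 for terminal/side/inner-Gly/inner vectors (`tail_defaults()`);
all overridable. Non-positive values inside the fit window shrink it with a
warning; an ACF that never reaches `P_cut` is an error (the record is too
short to support the extension).

The spectral density `J(ω) = 2∫₀^∞ P₂(t)cos(ωt)dt` integrates the head by
the *exact cosine transform of its piecewise-linear interpolant* (a
Filon-type rule) and the tail analytically (the Lorentzian piece is exact).
Plain trapezoidal quadrature loses ~1% at ωτ ≈ 10² where J is small; the
piecewise-linear transform's error is that of linear interpolation alone,
independent of frequency, and the tests hold it to 0.5% over four decades.
A fully numeric mode (`mode = "numeric"`) integrates the evaluated two-part
function instead, for cross-checking.

The reduced susceptibility-representation rate is
`1/T₁ᴴ(ω) = ω[J(ω) + 4J(2ω)]`. For a single-exponential ACF this is
`2ωτ/(1+(ωτ)²) + 8ωτ/(1+(2ωτ)²)` with its maximum at `ω_max·τ = 0.61580`;
one printed variant of this closed form circulates with the second
amplitude garbled, and the implemented form is fixed by consistency with
the definition (it reproduces `ω_max·τ ≈ 0.62` under brute-force
maximisation, which the tests verify). `ω_max` is refined from the grid
argmax by a local quadratic fit in log-frequency; the default grid is 400
log-spaced points over 1e5–1e12 rad/s. Physical rates at a spectrometer
frequency follow from `1/T₁ = (A₀/ω_H)·1/T₁ᴴ(ω_H)` with the theoretical
CH₂ prefactor `A₀ = 0.56e10 s⁻²` as default and `0.88e10 s⁻²` as the
calibrated value used for pooled terminal+side vectors; `A₀` is
configuration, never fitted inside the package. Pooling of equivalent
vector classes is vector-count-weighted (`pool_acfs()`).

## What the synthetic generators emulate — and what they do not

Every generator takes a mandatory seed, restores the caller's RNG state,
and is bit-reproducible.

**Rigid rotor.** Isotropic rotational diffusion is propagated by a random
rotation *vector* with i.i.d. Gaussian components of variance `2·D_r·dt`
applied via Rodrigues' formula with renormalisation. In the small-step
limit this gives exactly `P₁ = exp(−2D_r t)` and `P₂ = exp(−6D_r t)`; the
often-quoted recipe "uniform axis, rotation angle of variance 2·D_r·dt"
underestimates the effective diffusion by a factor of three and was
rejected in favour of the propagator that honours the stated correlation
times. The stability guard `D_r·dt < 0.05` keeps the small-angle regime.

**Counterion ensemble.** Metropolis sampling of point counterions
(charge −1) confined to the cubic cell around a macroion of charge +Q
smeared uniformly in a sphere, with pairwise Coulomb energy in units of
`kBT` through λ_B, non-periodic within the cell — consistent with the
finite-cell `ψ(D) = 0` framing of the potential analysis, and deliberately
simpler than Ewald summation. Acceptance outside [0.1, 0.9] warns. The
macroion appears in the output as Q unit-charge beads at fixed
uniform-in-sphere positions so charge profiles see both species. Two
consequences are worth knowing. First, a uniformly charged penetrable
sphere has its potential minimum at the centre, so the ensemble develops a
small, real osmotic counterion excess in the innermost bins — the
double-layer contract (one sign change of q(r) into the negative shell) is
therefore asserted from the net-charge maximum outward on coarse bins.
Second, the fixture has no solvent structure, no dielectric discontinuity
and no molecular flexibility, so it validates the *analysis chain*
(binning, cumulative charge, Poisson solve, renormalization theory), not
absolute dendrimer observables.

**Bead dendrimers.** A second-generation tree: core, two branches per
branching point through three subgenerations, a two-residue spacer before
every branching point and terminal residue, eight terminal residues each
with two charged end nitrogens (16 charged end groups). The charged-spacer
preset carries +1 per inserted residue (bare charge +44); the neutral-spacer
preset leaves insertions neutral (+16); counterions equal the bare charge.
The embedding is a self-avoiding random walk at fixed bond length — adequate
for topology/selection/profile plumbing, not a conformational model.

**Hydrogen-bond fixtures.** Each frame contains the scheduled number of
qualifying triples plus three decoys violating exactly one rule each
(distance 0.40 nm; angle 45°; distance exactly at the 0.35 nm boundary,
excluded by strictness). The boundary decoy is kept in exact-arithmetic
position so the strict inequality is exercised deterministically.

Passing tests on these generators therefore demonstrates correctness of the
estimators and solvers under known statistical structure; they do not
demonstrate force-field realism, solvent effects, or the absolute values of
any published simulation.

## Problem sizes and numerical tolerances

The statistical test fixtures use 15–60 k rotor frames with 32–64 vectors,
and counterion ensembles of 40–100 decorrelated frames after a few hundred
burn-in sweeps — sizes chosen so the 1/e-time recovery sits comfortably
inside 3% and theory-vs-ensemble effective charges inside 0.15·Q_bare,
while a full suite run stays in the low minutes. Root finding converges to
1e-10 residuals, SOR to 1e-9 increments, oracle-equivalence checks to
1e-12. Degenerate inputs fail loudly: empty systems, zero masses, shuffled
time stamps, non-neutral charge profiles, coincident Rh pairs, ACFs that
never reach 1/e or `P_cut`.

## Known limitations

- No Ewald electrostatics in the MC fixture; no added salt anywhere; no
  dielectric discontinuity at the macroion boundary.
- The Poisson solver consumes the *measured* charge profile — it is not a
  Poisson–Boltzmann self-consistency loop.
- Hydrodynamics stop at the Kirkwood double sum; no bead-shell models.
- Bond lifetimes/kinetics of hydrogen bonds are out of scope (counts only).
- `A₀` is metadata; no dipolar first-principles derivation is attempted.
- XTC/TRR/DCD binary readers are not bundled; PDB (via bio3d), GRO and the
  documented plain-text dialect cover structure and frames, and the
  plain-text dialect is the tested interchange format.
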