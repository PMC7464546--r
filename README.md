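# dendritraj

Analysis toolkit for molecular-dynamics trajectories of charged peptide
dendrimers and similar penetrable macroions in salt-free solution, with
deterministic synthetic generators so every stage can be exercised and
validated without production MD data.

## What it computes

Charged dendrimers in water attract their counterions: some ions condense
into contact pairs with the protonated amine groups, some remain "osmotic"
inside the molecule and stretch it, and the rest form a diffuse double layer
that sets the zeta potential. `dendritraj` implements the complete analysis
layer connecting an atomistic trajectory to these observables:

**Conformation.** Mass-weighted radius of gyration
`Rg = sqrt(Σ mᵢ rᵢ² / M)`, the unweighted gyration tensor
`A_μν = (1/N) Σ (μᵢ−μ_c)(νᵢ−ν_c)` with asphericity
`α = 1 − 3(I_x I_y + I_x I_z + I_y I_z)/(I_x+I_y+I_z)²`, the Kirkwood
hydrodynamic radius `R_h = ⟨1/r_ij⟩⁻¹`, the end-group radius
`R_e = sqrt(⟨r²⟩_ends)`, the rigid-sphere boundary `√(5/3)·Rg`,
min–max size-fluctuation statistics, and spacer end-to-end distributions.

**Radial structure.** Density `ρ(r)`, terminal-nitrogen counts `n_t(r)`,
the N⁺–counterion pair RDF `g(r)` with first-peak ion-pair counting, the net
charge profile `q(r) = n₊(r) + n₋(r)`, its running integral `Q(r)`, and the
effective charge/radius `(Q*, R_max)` at the maximum of `Q(r)`.

**Electrostatics.** Bjerrum length `λ_B = e²/(4π ε ε₀ k_B T)`, the
spherically symmetric Poisson equation
`ψ'' + (2/r)ψ' = −4π λ_B ρ_q(r)` with `ψ(D) = 0` solved by two independent
routes (Green's-function quadrature and SOR relaxation), the zeta potential
`ζ = Ψ(R_max)`, surface charge density `σ = Q*/(4π R_max²)`, the soft-sphere
charge-renormalization relation
`Q* = (R/λ_B)(1/2ν) ln[(Q/Q*−1)(D³/R³−1)]`, and the osmotic-ion count
`n_osm = Q_bare − Q* − ⟨n_pairs⟩`.

**Hydrogen bonds.** Geometric criterion (donor–acceptor distance < 0.35 nm
and angle < 30°, strict), per-frame count distributions for
intra-solute and solute–water bonds.

**Dynamics and NMR relaxation.** FFT autocorrelation functions of scalars
and of unit vectors at Legendre orders 1 and 2, 1/e relaxation times, the
rigid-body relation `P₂ = P₁³` and `τ_rot = τ_P1/3`, exponential tail
extension of `P₂(t)`, the spectral density `J(ω) = 2∫P₂(t)cos(ωt)dt`
(exact piecewise-linear cosine transform plus analytic Lorentzian tail), the
reduced spin-lattice rate `1/T₁ᴴ = ω[J(ω) + 4J(2ω)]` with its maximum
`ω_max τ ≈ 0.62`, and physical `1/T₁` temperature series at a fixed
spectrometer frequency via `1/T₁ = (A₀/ω_H)·1/T₁ᴴ`.

**Synthetic data.** Rigid-rotor vector trajectories with prescribed
rotational diffusion (P₁/P₂ decay times `1/(2D_r)`, `1/(6D_r)`), Metropolis
counterion ensembles around a uniformly charged sphere, bead dendrimer
topologies with the Lys-2Lys (+44 e) and Lys-2Gly (+16 e) compositions, and
hydrogen-bond geometry fixtures with scheduled bond counts. All generators
are pure functions of their seed.

## Worked example

Counterion condensation around a +44 e macroion (radius 3.14 nm) in a
7.5 nm cell at body temperature, compared against charge-renormalization
theory:

```r
library(dendritraj)

mc <- counterion_mc(Q = 44, R_sphere = 3.14, cell_edge = 7.5,
                    lambda_B = 0.7, n_frames = 100, seed = 42)
cp <- charge_profiles(mc$trajectory, mc$topology, dr = 0.05)
cp$effective
#> # A tibble: 1 × 2
#>   Q_star R_max
#>    <dbl> <dbl>
#> 1   14.9  3.22

D <- sqrt(3) * 7.5 / 2
field <- solve_poisson_spherical(cp$q, D, lambda_B = 0.7, T = 310)
zeta_potential(field, cp$effective$R_max)          # 16.62 mV
surface_charge_density(cp$effective$Q_star,
                       cp$effective$R_max)         # 0.114 e/nm^2

glance(charge_renormalization(Q = 44, R = cp$effective$R_max,
                              D = D, lambda_B = 0.7))
#> # A tibble: 1 × 3
#>   Q_star Q_ratio residual
#>    <dbl>   <dbl>    <dbl>
#> 1   11.5   0.262        0
```

The ensemble's measured effective charge (14.9 e, i.e. 34% of the bare
charge survives outside the condensed layer) sits close to the analytic
soft-sphere prediction (11.5 e); the remaining ~27 ions are osmotic or
paired. The same pipeline on an orientational problem:

```r
rt <- rigid_rotor_trajectory(Dr = 0.25, n_frames = 20000, dt = 0.01,
                             n_vectors = 64, seed = 42)
p2 <- acf_orientational(rotor_vectors(rt), order = 2, dt = 0.01,
                        max_lag = 2000)
relaxation_time_1e(p2)                      # 0.666 ns  (theory 1/(6 Dr) = 0.667)

ext <- extend_acf_tail(p2, P_cut = 0.04, n_approx = 100)
t1  <- reduced_t1(ext, omega_grid_default(300, 1e7, 1e11))
attr(t1, "omega_max")                       # 9.38e8 rad/s  (0.6158/tau2 = 9.24e8)
autoplot(t1)
```

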