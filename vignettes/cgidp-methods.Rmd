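---
title: "Coarse-grained modelling of disordered-protein phase behaviour with cgidp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained modelling of disordered-protein phase behaviour with cgidp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgidp)
```

## The model

`cgidp` represents a disordered protein as one bead per residue, centred on
the Cα position, in an implicit solvent. Three terms define the potential
energy:

**Nonionic contacts** use the Ashbaugh–Hatch form: a Lennard-Jones
potential $u_{LJ}(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ whose
attractive tail is scaled by a per-pair stickiness
$\lambda_{ij} = (\lambda_i + \lambda_j)/2$, with
$\sigma_{ij} = (\sigma_i + \sigma_j)/2$. Below the potential minimum
$2^{1/6}\sigma$ the full repulsion acts and the constant
$(1-\lambda)\epsilon$ keeps the curve continuous; above it the tail is
multiplied by $\lambda$; the whole curve is truncated and shifted to zero at
a cutoff $r_c$. At $\lambda = 1$ this is the truncated-shifted
Lennard-Jones potential; at $\lambda = 0$ it is purely repulsive. Some
typeset statements of this potential leave $\epsilon$ out of the bracket
and write the inner constant as a bare $(1-\lambda)$; we implement the
dimensionally consistent form with $\epsilon$ restored in both places
($\epsilon$ = 0.8368 kJ/mol throughout).

**Electrostatics** between average residue charges use the Debye–Hückel
potential $u_{DH}(r) = q_i q_j \frac{e^2}{4\pi\epsilon_0\epsilon_r}
\frac{e^{-r/D}}{r}$, truncated and shifted at 4 nm independent of the
nonionic cutoff. The dielectric constant comes from an empirical
liquid-water polynomial in $T$ (valid 250–400 K; refused outside), the
Debye length from $D = (8\pi\lambda_B n_s)^{-1/2}$ with the salt number
density $n_s$ of a monovalent electrolyte at the stated molar ionic
strength. Aspartate/glutamate carry −1, lysine/arginine +1, histidine a
Henderson–Hasselbalch average charge with pKa 6. Temperature enters only
through $\epsilon_r(T)$ and the thermal prefactor: between 4 °C and 50 °C
the Debye length changes by only about −3%, and the pair energy of unit
charges at the 4 nm cutoff and 150 mM is 2.6–2.8 J/mol — three orders of
magnitude below $k_BT$, which justifies the truncation at physiological
salt. At 10 mM the same energy is ~43 times larger, so low-salt predictions
are sensitive to the electrostatic cutoff (a 6 nm option exists).

**Bonds** between consecutive beads are harmonic,
$u = \tfrac12 k (r - r_0)^2$ with $k$ = 8033 kJ mol⁻¹ nm⁻² and $r_0$ =
0.38 nm. Nonbonded terms are excluded for directly bonded (1–2) pairs, so a
two-bead chain's potential energy is exactly the bond term — a property the
test suite uses to validate the sampler against the analytic Boltzmann
distribution.

### Parameter tables

Bead diameters are the van der Waals values; masses are standard residue
masses; two stickiness scales ship with the package: `CALVADOS1` (intended
with a 4 nm nonionic cutoff) and `CALVADOS2` (re-optimized for a 2 nm
cutoff). Loaders refuse incomplete tables rather than imputing. The
N-terminal amine and C-terminal carboxyl are ionized at the pH range these
systems are studied at, so by default the first bead of each chain gains +1
and the last −1; published descriptions of the model family are silent on
this detail, hence the `termini_charges` flag supports the strict
internal-residue-only reading as well.

## Simulation protocol

Dynamics are NVT Langevin with a 10 fs time step and friction 0.01 ps⁻¹.
The named integrator leaves the splitting open; we use BAOAB because it
gives accurate configurational averages at this step size. Single chains
start fully extended in a cubic box of side $0.38(N-1) + 4$ nm; the
sampling schedule saves a frame every $3N^2$ fs (N > 100) or 30 ps
(otherwise), runs ten replicas of 600 frames, and discards the first 100
per replica — 5,000 weakly correlated conformations per sequence. Slab
(direct-coexistence) systems place ~100 extended chains along z with middle
beads at random xy positions at least 0.7 nm apart, in boxes of
[15, 15, 150] nm (up to [25, 25, 300] nm for the longest chains), run for
microseconds and discard the first 0.6 µs.

The integrator draws all randomness from R's RNG: a run with a fixed seed
is bitwise reproducible, and replica seeds derive from a master seed by a
simple counter. Overlapping nonbonded beads (r < 10⁻⁴ nm) abort with the
offending pair named rather than propagating non-finite forces.

Two energy paths exist deliberately: the compiled engine (Rcpp) used for
dynamics, and a vectorized pure-R reference (`system_energy`). They must
agree to 1e-9 relative — the suite also checks both against an independent
27-image brute-force oracle.

## Single-chain observables

The radius of gyration is mass-weighted by default (residue masses from the
table) and the chain is unwrapped across periodic boundaries first; a
uniform-weight option exists because published practice does not always
state the weighting. Both $\langle R_g\rangle$ and
$\sqrt{\langle R_g^2\rangle}$ are reported: the rms is systematically the
larger of the two (Jensen), and which of them a model was calibrated
against matters at the few-percent level — the same level as cutoff
effects.

Statistical errors of time averages use the Flyvbjerg–Petersen blocking
transform. The series is pairwise-averaged repeatedly; the naive standard
error per level rises to a plateau once blocks exceed the correlation time.
We take the first level statistically consistent with the next two (within
twice the combined level uncertainties), falling back to the maximum over
levels when no plateau is found — a conservative choice for short series.
On iid data this reproduces $\sigma/\sqrt{n}$ within sampling scatter; on
AR(1) data with $\phi = 0.9$ it recovers the analytic
$\sigma\sqrt{(1+\phi)/(1-\phi)/n}$ within ~30%.

Model–experiment discrepancies use
$\chi^2_{R_g} = [(R_g^{exp} - R_g^{calc})/\sigma^{exp}]^2$ and, for
paramagnetic relaxation enhancement (PRE) data, the mean squared
standardized residual over the label × residue matrix. Real PRE matrices
have gaps; masked entries leave both the sum and the normalization, which
reduces to the printed $1/(N_{labels} N_{res})$ form on complete matrices.
The forward model mapping coordinates to PRE observables is intentionally a
pluggable input — per-frame observables are consumed, not computed.

## Slab analysis

Translation along the periodic z axis is a pure gauge, so each frame is
centred by the circular shift that maximizes the mass inside a central
window of half the box length (computed on a coarse 1 nm histogram, then
refined by the mass-weighted mean of the window content). The published
protocol cites an earlier centering procedure without details; this
estimator is our own, chosen for robustness to dilute-phase noise, and the
pipeline downstream of it is translation invariant by construction.

The time-averaged mass density $\rho(z)$ (mg/mL, 1 nm bins by default,
mass-conserving by construction) is fitted per semi-profile (z > 0 and
z < 0) with
$\rho(z) = \frac{\rho_a+\rho_b}{2} + \frac{\rho_b-\rho_a}{2}
\tanh\!\big(\frac{|z| - z_{DS}}{t}\big)$,
averaging parameters over the two sides. Phase concentrations then average
the profile over $|z| < z_{DS} - t/2$ (condensed) and $|z| > z_{DS} + 6t$
(dilute) and convert to molar units with the chain mass. One published
sentence pairs the dilute/dense labels with these regions in the opposite
order; since the slab sits at the box centre by construction, we assign the
central region to the dense phase. A fit that does not converge, or whose
plateaus differ by less than a factor of 5, is reported as "no phase
separation detected" rather than an error; an empty dilute region yields
c_sat = 0 with a flag. Uncertainties come from blocking over per-frame
region averages.

Cutoff-difference accounting (`cutoff_energy_difference`) measures the bare
(unshifted) nonionic energy per protein that a shorter cutoff discards —
the pair sum over $r_c^{small} < r \le r_c^{large}$ — which in condensed
phases amounts to several $k_BT$ per chain even though each individual pair
at 2 nm contributes only ~5 J/mol. The package validates this accounting
exactly against restricted-pair enumeration on desk-scale fixtures; the
published cluster-scale estimate (13 ± 1 kJ/mol per protein across four
slab systems) requires multi-microsecond 100-chain trajectories and is not
recomputed in the test suite.

## Stickiness optimization

The learner minimizes
$\mathcal{L}(\lambda) = \langle\chi^2_{R_g}\rangle +
\eta\langle\chi^2_{PRE}\rangle - \theta\ln P(\lambda)$ with $\eta = 0.1$,
$\theta = 0.05$, averaging per data class with uniform weights across
proteins (the weighting across proteins is not specified in print; uniform
is the natural reading of the angle brackets).

**Prior.** $P(\lambda)$ is a Gaussian kernel density estimate (bandwidth
0.05) over min-max-normalized hydrophobicity scales;
hydrophilicity-oriented scales are flipped as $1-x$ after normalization and
affine duplicates collapse to one representative. The full published prior
uses 70 scales whose numeric values live in the cited literature; the
package bundles a small curated subset of six classic scales as example
input and accepts any table in the same schema. Log-densities use a
log-sum-exp so evaluation is finite everywhere; severe underflow clamps to
a large negative penalty with a warning.

**Reweighting.** Because the nonionic energy is affine in each pair
stickiness, a frame's energy is affine in the whole λ vector:
$U(\lambda) = c + M\lambda$. `lambda_energy_coefficients` accumulates
$(c, M)$ once per frame, after which the Boltzmann weights
$w_i \propto e^{-[U_i(\lambda_k)-U_i(\lambda_0)]/k_BT}$ for any trial set
are a matrix–vector product. Electrostatics are λ-independent and cancel.
$k_BT$ uses each protein's own training temperature. The effective fraction
$\phi_{eff} = \exp[-\sum_i w_i \ln(w_i N)]$ is computed with normalized
weights, making it exactly 1 at uniformity and $1/N$ at single-frame
support; the printed expression mixes normalized weights with an $\times N$
factor, and this normalized reading is the one under which it behaves as an
"effective fraction". Trial sets whose worst-protein $\phi_{eff}$ drops
below 60% are rejected untested.

**Search.** Proposals nudge five random residues by N(0, 0.05²) (clamped to
[0, 1]); acceptance is Metropolis with control parameter ξ, which starts at
0.1 and shrinks by 1% per iteration until 10⁻⁸ — 1604 iterations per
micro-cycle, ten micro-cycles per cycle, ξ resetting at each micro-cycle
(the printed schedule can be read either way; per-micro-cycle reset is the
literal reading and is configurable). After a cycle the lowest-cost vector
is kept and, given a re-simulation hook, the next cycle rebuilds the
ensembles there.

## The synthetic-data generators, and what passing tests mean

Fixtures are generated in code, seeded, and never downloaded:

- `generate_tanh_fixture` produces exact (optionally noisy) interface
  profiles, and bead clouds realizing them, for the centering/fitting
  pipeline. It emulates the shape and noise of equilibrium slab profiles
  but not their dynamics or finite-size drifts.
- `generate_ar1_series` provides scalar series with a known correlation
  structure for the autocorrelation and blocking estimators.
- `generate_toy_training_set` builds a miniature, fully controlled version
  of the parameter-learning problem: a three-letter alphabet (A, G, Y),
  four 14-residue chains each biased towards one letter, simulated at a
  known stickiness vector λ*. Its defaults are the study conditions of the
  recovery test: ε = 2 kJ/mol (stronger contacts make ⟨R_g⟩ respond to λ on
  a 14-mer the way longer real chains do at the standard ε), 2 nm cutoff,
  298 K, 150 mM, 600,000 steps per chain with frames every 10 ps and the
  first 100 discarded, and σ_exp = 0.015 nm, matching the sampling
  precision of the reference simulations (no extra noise is injected — the
  seed-to-seed scatter of the reference run plays the role of measurement
  error). Under these conditions the optimizer recovers λ* to within 0.1
  per coordinate starting from 0.5, using four cycles of two micro-cycles.

These fixtures establish correctness of the machinery — estimators against
closed forms, samplers against Boltzmann distributions, the optimizer
against a known ground truth. They do not establish predictive accuracy on
real proteins: that depends on the published parameter tables and on
cluster-scale simulations (55-protein training sets, multi-microsecond
slabs) outside the scope of a test suite. Problem sizes in the suite —
24-mers for sampling checks, 14-mers for reweighting and recovery, single
frames for energy oracles — were chosen as the smallest systems in which
each property is non-trivially exercised.

## Numerical choices and edge cases

- Units: nm, ps, Da, kJ/mol ($k_B$ = 0.008314462618 kJ/mol/K); Coulomb
  constants from CODATA 2018. Cutoff-boundary energies are reported in
  J/mol where small.
- Minimum-image convention requires every box edge to be at least twice
  the largest cutoff; violations are refused, not silently wrapped.
- Ionic strength 0 returns an infinite Debye length (documented sentinel).
- A constant series has no autocorrelation (error) but a zero blocking
  error.
- Tanh fits start from profile-derived guesses, bound t > 0, and treat
  non-convergence as "no phase separation", not failure.
- `propose_lambda` clamps to [0, 1]; the table invariant allows
  [−0.2, 1.2] so vendored scales slightly outside [0, 1] remain loadable.

## Known limitations

No pressure coupling, constraints, hydrodynamics, explicit ions, or Ewald
electrostatics; folded domains and post-translational modifications are out
of scope. The pairwise kernels are $O(N^2)$ per step — ample for the chain
sizes above, but production slab studies at 100 chains × hundreds of
residues belong on specialized MD engines, with this package consuming
their trajectories. c_sat estimates inherit the finite-size and
equilibration caveats of the slab geometry; equilibrium detection is left
to the user.
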