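---
title: "Accelerated surface-hopping dynamics of intersystem crossing on model vibronic Hamiltonians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated surface-hopping dynamics of intersystem crossing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinhop)
```

## The problem

Heavy-atom photosensitizers (iodinated BODIPY dyes are the motivating
family) convert absorbed photons into triplet excitations through
intersystem crossing (ISC), the spin-forbidden radiationless transition
mediated by spin-orbit coupling (SOC). ISC in such dyes happens on the
picosecond scale — far beyond what direct nonadiabatic molecular dynamics
can routinely sample — while the spin-allowed internal conversions are
femtosecond-fast. `spinhop` implements the simulation machinery for this
regime on *model* vibronic Hamiltonians: fewest-switches surface hopping
(FSSH) in the spin-adiabatic basis, SOC scaling with lifetime extrapolation,
Wigner-sampled initial conditions, nuclear-ensemble spectra, and the kinetic
bookkeeping (triplet quantum yield, Einstein emission rate) that turns
fitted lifetimes into photophysical observables.

Everything ab initio is out of scope by design. The electronic structure is
a linear vibronic coupling (LVC) surrogate whose parameters (vertical
energies, gradients, couplings, SOC magnitudes) the user supplies or draws
from the built-in fixture generator; published excitation energies appear
only as fixture inputs, never as computed results.

## The model layer

A `model_system` couples:

* harmonic **modes** — frequency (cm^-1), reduced mass (amu), equilibrium;
  coordinates and momenta are handled in atomic units throughout, with eV,
  cm^-1, fs and amu at every interface (CODATA 2018 conversions,
  `physical_constants()`);
* a scalar **electronic** block — vertical energies at the origin with the
  shared harmonic baseline, per-state linear terms $\kappa$ and same-spin
  interstate couplings $\lambda$ (the standard LVC form), so evaluation at
  the origin reproduces the vertical energies exactly and all gradients are
  analytic;
* a **SOC** block — complex couplings between singlets and the three $M_S$
  components of each triplet (we label components $M_S = -1, 0, +1$; the
  choice between $M_S$ and Cartesian labelling is pure bookkeeping, and we
  fix one), optionally with linear/quadratic magnitude modulation along a
  named coordinate. That mirrors the observed geometry dependence of SOC in
  near-planar chromophores, where losing planarity mixes $(n,\pi^*)$ and
  $(\pi,\sigma^*)$ character into the $(\pi,\pi^*)$ states and SOC grows
  with the out-of-plane distortion.

The spin-diabatic basis is ordered singlets first (ascending vertical
energy), then triplets in contiguous three-component blocks; its dimension
is $n_S + 3 n_T$. A 7-singlet/10-triplet system, the size used for
chromophore-like simulations, gives dimension 37.

At each geometry the same-spin blocks are diagonalized first; the resulting
scalar (spin-free adiabatic) states are what the field calls spin-diabatic
states $\Theta$, and the SOC matrix is rotated into that basis. The
two-component Hamiltonian is then
$$\mathbf{H} = \mathrm{diag}(E^{\text{scalar}}) + \alpha\,V_{\text{SOC}},
\qquad \mathbf{H}\mathbf{U} = \mathbf{U}\mathbf{E},$$
with $\alpha$ the SOC scaling factor. Diagonalization yields the
spin-adiabatic states $\Phi = \Theta U$. This first-order
quasi-degenerate perturbation theory is nothing more than a truncated
spin-orbit CI; no orthonormalization step is needed here because the model
basis is orthonormal by construction.

## The dynamics

`run_trajectory()` realizes a three-step integrator:

1. **nuclear step** — velocity Verlet (default $\Delta t = 0.5$ fs) on the
   active spin-adiabatic surface, with the exact Hellmann-Feynman force
   evaluated in the coordinate-independent diabatic basis;
2. **electronic structure** — diagonalization at the new geometry, then
   gauge alignment: columns are matched to the previous step by maximal
   absolute overlap (undoing trivial-crossing swaps) and phases rotated so
   diagonal overlaps are real non-negative; near-degenerate clusters
   (gap < 1e-10 hartree) are aligned jointly through the polar factor of
   the overlap block to avoid arbitrary mixing;
3. **electronic propagation and hopping** — the coefficient vector $c$ is
   advanced through 20 substeps (0.025 fs) with energies and
   time-derivative couplings linearly interpolated between the two nuclear
   steps; each substep applies the exact unitary exponential of
   $-(i\,\mathrm{diag}(E) + T)\,h$. Couplings come from the antisymmetrized
   finite-difference overlap
   $T_{jk} = (\langle\phi_j(t)|\phi_k(t+\Delta t)\rangle -
   \langle\phi_k(t)|\phi_j(t+\Delta t)\rangle)/2\Delta t$.
   Fewest-switches outflow from the active state is accumulated over the
   substeps and one hop decision is made per nuclear step by cumulative-
   probability roulette.

No decoherence correction is applied anywhere: the coefficient vector is
never damped. Populations reported per trajectory are the spin-diabatic
$|b_i|^2$ with $b = Uc$, summed over the three components of each triplet,
and `ensemble_populations()` averages them over trajectories.

Two choices the method leaves open are fixed as documented conventions, not
reproductions of any reference code: accepted hops rescale the *full*
momentum vector by a single scalar so total energy is conserved exactly
(well-defined for models of any dimension), and frustrated hops — upward
hops the kinetic energy cannot cover — are rejected with momenta unchanged
(no reversal). Both are logged per event.

The per-trajectory propagation loop is compiled (RcppArmadillo),
specialized to the LVC family; the exported single-step operations
(`nuclear_step()`, `tdc_estimate()`, `electronic_propagate()`,
`hop_probabilities()`, `apply_hop()`) are the same algorithm exposed
piecewise for testing and custom loops, and the test suite pins the
compiled core against them.

## Initial conditions

`sample_wigner()` draws coordinates and momenta from the Wigner
distribution of the canonical harmonic ensemble: independent Gaussians with
$\sigma_q^2 = \frac{\hbar}{2m\omega}\coth\frac{\hbar\omega}{2k_BT}$ and
$\sigma_p^2 = \frac{m\omega\hbar}{2}\coth\frac{\hbar\omega}{2k_BT}$,
the zero-point widths at $T = 0$ and the classical limits at high
temperature; 298 K is the default. Each ensemble member derives its RNG
stream from (seed, index), so ensembles are reproducible member by member.
Trajectories start in the quasirelativistic state with the largest overlap
with the requested spin-diabatic state (S1 by default), with $c$ set to
that basis vector.

## Accelerated ISC and extrapolation

Weak-coupling (golden-rule) rates are proportional to the squared coupling,
so scaling SOC by $\alpha > 1$ — leaving the nonadiabatic couplings
untouched — accelerates ISC by $\alpha^2$:
$\tau_\alpha = \tau_1\,\alpha^{-2}$, a straight line of slope $-2$ in
$\log\tau$ vs $\log\alpha$. The standard protocol runs ensembles at
$\alpha = 2, 3.5, 5$ (20 trajectories each, 200/200/100 fs horizons — all
defaults in `run_ensemble()` and `load_run_config()`), fits growth or decay
curves, and extrapolates back to $\alpha = 1$.

`extrapolate_to_unit_alpha()` fits the log-log line with a **free** slope.
Finite ensembles produce lifetime triples that deviate substantially from
the ideal law (published triples of this kind imply slopes between about
-3.3 and -4.0), and only the free-slope fit makes extrapolated lifetimes
reproducible from the fitted time constants; the slope is reported
alongside $\tau_1$ so its deviation from $-2$ is always visible.
`fit_growth()` fits $A(1 - e^{-(t - t_0)/\tau})$ with $A \in [0, 1]$ and
free onset $t_0$; `fit_decay()` fits $B + A e^{-(t-t_0)/\tau}$ with $t_0$
pinned to the first time point, because for a pure decay a free $t_0$ is
redundant with $A$ ($A$ absorbs $e^{t_0/\tau}$) and fitting both would be
unidentifiable. Initial guesses come from the 10%/90% crossing times.
Lifetimes convert to rates as $k = 1/\tau$ (`rate_from_lifetime()`).
We note one published inconsistency surfaced by this convention: a triplet
time-constant extrapolation of 6.06 ps corresponds to
$k_{ISC} = 1.65\times10^{11}\,\mathrm{s^{-1}}$, while the adjacent printed
rate is $1.73\times10^{11}\,\mathrm{s^{-1}}$; the package implements
$k = 1/\tau$ and leaves the discrepancy visible.

```{r extrapolation}
ex <- extrapolate_to_unit_alpha(c(2, 3.5, 5), c(441.66, 28.44, 12.44))
glance(ex)
```

The triplet quantum yield combines the fitted rates,
$\Phi_T = k_{ISC}/(k_{ISC} + k_{IC} + k_F)$, with the fluorescence rate
from Einstein's spontaneous-emission coefficient
$k_F = 2\pi e^2 E_F^2 f / (h^2 \varepsilon_0 m c^3)$:

```{r yield}
k_f <- einstein_rate(2.56, 0.58)
k_f
triplet_quantum_yield(k_isc = 1.65e11, k_ic = 2.5e10, k_f = k_f)
```

When extracting $k_{IC}$ from ensembles, we define it as the fitted S1
depletion rate multiplied by the fraction of S1 out-flux ending in singlet
states, counted from hop-character weights — an explicit artifact
convention, since hop-based counting cannot see character transfer that
happens by continuous remixing inside one spin-adiabatic state (a known
limitation of the hop-character picture; the diagonal entries it produces
are an artifact of the same bias).

## The golden-rule fixture: what it emulates and what it does not

`generate_fixture("two_manifold_golden_rule")` is the validation model for
the $\alpha^2$ law, and its construction is instructive about what FSSH
needs to show golden-rule kinetics:

* **A displaced donor.** The S1 minimum is shifted away from the
  Franck-Condon point along a 1000 cm^-1 tuning mode, so every trajectory
  sweeps through all singlet-triplet crossings twice per 33 fs period at
  high velocity, while the initial region keeps the S/T diabatic gap far
  above $\alpha V$ (the initial state is pure S1). Putting a crossing at
  the sampled origin instead produces initially spin-mixed states.
* **An acceptor manifold.** A single acceptor triplet does not decay: the
  three components act as one bright channel and the coherent dynamics
  equilibrates at 50/50 like a two-level system. Five triplets with
  staggered crossing points (1.90-2.50 eV, $\kappa_T = -1$ eV/au) make the
  transfer effectively irreversible.
* **Dephasing.** With no decoherence correction, repeated passages
  interfere (Stueckelberg oscillations) and the fully coherent 1-mode model
  shows a weak-coupling rate suppressed below the golden-rule limit (log-log
  slopes near -2.7). A second, thermally active 400 cm^-1 mode that
  modulates the triplet energies with staggered signs restores
  golden-rule kinetics by gap-fluctuation dephasing — the same physics that
  makes real polyatomic ISC rate-like.
* **Weak channels.** SOC is 28 cm^-1 per component, keeping the
  Landau-Zener per-passage probability small even at $\alpha = 3$, and the
  shortest lifetime above two vibrational periods so decay is not limited
  by the transit time to the crossings.

With these choices, lifetimes fitted at $\alpha = 1, 2, 3$ (about 620, 125
and 64 fs in the suite's ensembles) lie on a free-slope log-log line of
slope $\approx -2.1$. For the consistency check against the direct
$\alpha = 1$ simulation, $\tau_1$ is extrapolated from the accelerated
ensembles along the *theoretical* slope $-2$ line (the geometric mean of
$\tau_\alpha\,\alpha^2$): with only two accelerated points, a free-slope
"fit" is exact interpolation and amplifies the few-percent lifetime
counting noise roughly threefold, whereas the law's own line averages it.
The two estimates agree to ~14%; the residual is real method physics —
even with bath dephasing, fully coherent FSSH retains some interference
suppression at the weakest coupling. The suite runs 200 trajectories at
$\alpha = 1$ and 400 at each scaled coupling with horizons of 2600/700/350
fs (at least four fitted lifetimes each; these sizes keep the whole suite
in a few minutes on one CPU while leaving the fits unbiased by
truncation).

What passing this suite does *not* show: anharmonicity, conical-
intersection topologies beyond LVC, solvent dissipation, vibrational energy
transfer out of the system modes, or any ab initio surface. The
`bodipy_like_37state` fixture is explicitly a synthetic stand-in — its
ladder is shaped after published-style vertical energies and its SOC
magnitudes are drawn from the qualitative selection-rule categories below —
so chromophore-specific outcomes (saturation levels, yield values) are not
reproduced at desk scale, only the methodology that would produce them
given a real backend.

## SOC selection rules

`classify_soc_pair()` encodes the one-center Slater-Condon analysis for
heavy main-group substituents as a transparent rule table: SOC between a
singlet and a triplet is large only when the states differ in a single MO
pair whose members carry strong admixtures of *different* (mutually
perpendicular) valence p orbitals of the *same* heavy atom. The categories
are anchored magnitudes — units of cm^-1 (e.g. between $(\pi,\pi^*)$
states, which share the same out-of-plane p), tens (closed shell vs
$(n,\pi^*)$), 1000-2000 (closed shell vs $(\pi,\sigma^*)$ with out-of-plane
heavy p in the $\pi$), and ~2300, the atomic iodine limit (closed shell vs
$(n,\sigma^*)$, both MOs essentially atomic). States differing in two or
more MO pairs, and near-degenerate pairs with the same occupations, are
suppressed to units. The familiar El-Sayed rules are the special case for
states differing in orbital type. Borderline shared-orbital cases (e.g.
$(\pi,\pi^*)$ vs $(\pi,\sigma^*)$ with a common source $\pi$) are encoded
as "moderate, text-derived" at tens of cm^-1. The classifier computes no
integrals; its role is fixture design and annotation of hop-character
reports.

## Spectra and curve metrics

`nea_spectrum()` implements the nuclear-ensemble approach: the
cross-section is the *average* over sampled configurations of
oscillator-strength-weighted unit-area Gaussians centred at the vertical
excitation energies. The default width is 0.05 eV (a user parameter; no
canonical value exists), and the energy-dependent physical prefactor is
reduced to arbitrary units — sufficient for peak positions and shift
comparisons, which is what ensemble spectra are used for here. NEA spectra
carry no vibronic fine structure by construction. The default ensemble
size used in demonstrations is 1,000 configurations at 298 K.

`non_parallelity()` compares two potential energy curves on a shared grid
(interpolation-free) as $NP = \max_R|f-g| - \min_R|f-g|$: zero for curves
differing by a constant shift, symmetric, and invariant under adding a
common curve — the standard scalar for "same shape, different level"
benchmarking of excited-state methods.

## Numerical choices and limitations

* Internal units are Hartree atomic units; interface units eV / cm^-1 /
  fs / amu / kelvin / degrees. Constants are CODATA 2018.
* Gauge alignment uses greedy maximal-overlap assignment (exact for the
  near-diagonal overlaps of 0.5 fs steps; exhaustively checked against
  brute-force permutation search up to dimension 6 in the tests).
* The electronic norm is monitored every nuclear step; drift beyond 1e-8
  triggers renormalization and is counted on the trajectory object (it does
  not occur on the shipped fixtures).
* Velocity Verlet at 0.5 fs conserves energy to ~$(\omega\Delta t)^2/8$ of
  the mode energy between hops; sharp avoided crossings transited in under
  a step add small random energy noise, as in any on-the-fly FSSH at this
  step size. Accepted hops conserve energy exactly by construction.
* Degenerate scalar energies at crossings are permitted in the model layer;
  all regularization lives in the gauge alignment.
* Dihedral angles are reported in [0, 360) with trans-planar at 180
  degrees; histograms default to 1-degree bins. Neither convention is
  physically privileged; both are fixed and documented.
* Rotations/translations are not modelled: modes are abstract oscillators.
  The mass-equalization trick sometimes used to tame hydrogen motion in
  soft-mode scans is unnecessary here for the same reason.
* JSONL is the canonical trajectory format (streamable, diffable); an
  HDF5 writer is intentionally not provided.
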