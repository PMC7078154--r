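---
title: "Models and methods in lvcdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in lvcdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`lvcdyn` simulates sub-picosecond photoinduced intersystem crossing (ISC)
and electron transfer with trajectory surface hopping on analytical linear
vibronic coupling (LVC) potential energy surfaces.  The package targets
systems like rhenium-carbonyl chromophores pi-stacked with a tryptophan
donor in a protein scaffold, where low-lying charge-separated (CS) states
with weak spin-orbit coupling compete with metal-to-ligand charge-transfer
(MLCT) states with strong spin-orbit coupling.  Everything downstream of
the electronic-structure calculation is covered: model definition and I/O,
Wigner sampling, vertical excitations and the absorption spectrum,
stochastic initial-state selection, surface-hopping propagation, and the
population / charge-transfer / kinetics / coherence analyses.  Ab initio
electronic structure itself (and the computation of charge-transfer
numbers from wavefunctions) is out of scope; a synthetic model generator
stands in for a TDDFT-derived parametrization.

# The LVC model

All potentials derive from one shared harmonic ground-state surface in
dimensionless mass-frequency-scaled normal-mode coordinates,

$$V_0(Q) = \sum_i \tfrac{\hbar\omega_i}{2} Q_i^2, \qquad
  Q_i = \sqrt{\omega_i/\hbar}\,\sum_\alpha K_{\alpha i}
        \sqrt{M_\alpha}\,(r_\alpha - r^{\mathrm{ref}}_\alpha).$$

The diabatic potential matrix is $V = V_0\,\mathbf 1 + W$ with
$W_{nn} = \epsilon_n + \sum_i \kappa^{(n)}_i Q_i$ and
$W_{nm} = \sum_i \lambda^{(n,m)}_i Q_i$.  The prefactor of the
coordinate definition is printed inconsistently across the LVC
literature; `lvcdyn` implements the standard $\sqrt{\omega_i/\hbar}$
scaling, the unique choice consistent with
$V_0 = \sum_i \hbar\omega_i Q_i^2/2$.

Three representations are used:

* **diabatic** — the basis in which the parameters are defined (states
  fixed to their character at the reference geometry);
* **MCH** — eigenbasis of the spin-free potential matrix, obtained per
  multiplicity block ("adiabatic but spin-free");
* **diagonal** — eigenbasis of the full spin-expanded Hamiltonian
  including spin-orbit coupling (SOC); surface hopping runs here.

Eigenvectors are ordered by ascending energy within each block; phases
are fixed by a non-negative overlap with the previous step (the identity
at the reference), and numerically degenerate clusters are ordered by the
index of the dominant diabatic component.  This continuity convention is
what makes local diabatization work; the standalone `time_overlap()`
utility additionally offers column phase alignment, but the propagator
itself must not re-phase against a near-zero overlap diagonal (states
swapping at a crossing), so it uses the raw Loewdin-orthonormalized
overlap.

Units: interfaces use eV, fs, Angstrom, amu and cm^-1; internal dynamics
uses eV/fs with $\hbar = 0.6582\,$eV fs; $Q$ and $P$ are dimensionless.
Nonadiabatic couplings near degeneracies (gap below $10^{-8}$ eV) are
capped and flagged; they are diagnostic only, since the propagation uses
overlaps, so the cap cannot corrupt the dynamics.

# Model truncation

`truncate_model()` implements the three standard cleanup steps applied to
raw LVC parametrizations: removal of low-frequency modes (strongly
anharmonic in reality, and a source of spuriously large $\lambda_i Q_i$
couplings at large displacements), removal of strongly mixed high-lying
states, and zeroing of the SOCs of the closed-shell ground state, which
DFT does not describe on the same footing as the response states (such
SOCs can create artificial ground-state/triplet crossings).

# Synthetic models

`generate_synthetic_model()` draws a complete model from a
`manifold_spec`.  The defaults encode the world the package is meant to
emulate and are not tuning knobs:

* class counts and vertical-energy ranges per multiplicity follow the
  packaged vertical-excitation fixture (19 excited singlets / 17 triplets:
  5/4 CS, 7/6 MLCT, 2/1 LLCT, 2/4 IL, 1/0 AMCS, 3/1 MC, 0/1 AC);
* CS states get a dominant Trp-to-Dmp charge-transfer weight drawn from
  [0.90, 0.97] (the fixture's CS rows carry more than 90% Trp-to-Dmp
  weight) and small oscillator strengths (at most 0.011); MLCT states get
  metal-to-Dmp weight and the largest oscillator strengths (up to 0.107);
* SOC scales per class: 0.04 eV (about 320 cm^-1) for metal-centred
  classes (MLCT, MC) — the magnitude expected near a third-row transition
  metal — and 0.001 eV for CS states, which are not localized on the
  metal; pairs couple with the geometric mean of their class scales.
  Elements are drawn complex Gaussian with Hermiticity enforced by
  construction;
* 192 modes drawn uniformly on [60, 3600] cm^-1 with masses from a
  CHNO+Re palette; $\kappa$ and $\lambda$ are zero-mean Gaussians with
  0.05 and 0.01 eV scales — typical magnitudes for a rigid aromatic
  chromophore.

Oscillator strengths are realised exactly through the ground-to-excited
transition dipoles, $|\mu_{0n}|^2 = 3 f_n / (2\Delta E_n)$ in atomic
units.  The generator does **not** reproduce any real parametrization:
its purpose is to give the pipeline statistically realistic inputs, so a
green test establishes correctness of the machinery, not chemical
accuracy of any particular molecule.

# Parametrization oracles

`parametrize_kappa()` projects oracle-supplied Cartesian excited-state
gradients onto the mode basis (minus the ground-state part);
`parametrize_lambda()` implements finite-difference diabatization from
wavefunction overlaps at geometries displaced by $\pm h$ (default
$h = 0.05$, the customary step in mass-frequency-weighted coordinates)
along each mode: the antisymmetric part of the two-sided overlap
difference estimates the derivative coupling, which multiplied by the
vertical energy gap yields $\lambda$.  Published descriptions of this
overlap-based procedure omit the working equations; the implementation
here is validated by an internal round trip (generate a model, expose its own
eigenvectors as the oracle, re-parametrize, compare), which is exact in
the linear regime and recovers couplings to 2% at the default step.

# Initial conditions

`sample_wigner()` draws $Q_i, P_i \sim \mathcal N(0, 1/2)$ per mode — the
Wigner distribution of the vibrational ground state of $V_0$ (zero
temperature; no thermal excitation, matching the ground-state-oscillator
convention).  `vertical_excitation()` evaluates MCH energies, oscillator
strengths $f = (2/3)\Delta E |\mu|^2$ and CT-class fractions at each
sample; `compute_spectrum()` convolves all lines with a Gaussian
(default FWHM 0.2 eV) and decomposes by CS (or MLCT+IL) fraction into
bins that sum to the total exactly.

`select_initial_states()` accepts each (geometry, state) pair inside the
excitation window (default 2.8-3.2 eV, i.e. 443-387 nm) with probability
$f/f_{\max}$, with $f_{\max}$ taken over the whole eligible set.  Whether the
acceptance probabilities should be renormalized per geometry or globally
is a genuine convention choice; global renormalization is implemented and
documented, and a
fixed-count mode (`n_select`) is offered because published protocols
often report an exact ensemble size (e.g. 200 trajectories).

# Surface hopping

One nuclear step of `propagate_trajectory()` (default $\Delta t = 0.5$
fs, $\delta t = 0.02$ fs electronic substeps, 1000 fs total):

1. velocity-Verlet on the active diagonal state's gradient.  The
   gradient uses the *diagonal approximation*: MCH Hellmann-Feynman
   gradients $g^{(n)}_i = (U^\dagger \partial_i V U)_{nn}$ weighted by
   $|U^{\mathrm{diag}}|^2$ — exact wherever the SOC mixing is locally
   constant, and the convention used by established surface-hopping
   codes;
2. new-step electronic structure (MCH eigenbasis, SOC transform, diagonal
   eigenbasis with phase continuity);
3. local diabatization: Loewdin-orthonormalized overlap $T$ between the
   step's diagonal bases (expressed in the fixed diabatic basis), then
   $c(t+\Delta t) = T^\dagger \prod_k e^{-i H(s_k)\delta t/\hbar}\, c(t)$
   with $H(s)$ interpolated linearly between $\mathrm{diag}(E(t))$ and
   $T\,\mathrm{diag}(E(t+\Delta t))\,T^\dagger$ (midpoint rule; the inner
   loop is compiled).  Each factor is an exact Hermitian exponential, so
   the propagator is unitary to machine precision;
4. fewest-switches hop: the probability of leaving the active state is
   its relative population decrease over the step,
   $\max(0, 1 - |c_a(t+\Delta t)|^2 / |c_a(t)|^2)$, distributed over the
   gaining states proportionally to their population inflow.  Several
   equivalent-in-expectation variants of the fewest-switches probability
   exist; this flux-balance form, the natural one for propagator-based
   (local-diabatization) integration, is the package's documented
   convention;
5. on an accepted hop the **full velocity vector** is rescaled by
   $\sqrt{1 + (E_a - E_b)/E_{\mathrm{kin}}}$; a negative radicand makes
   the hop frustrated (velocities kept by default; reversal available);
   a downward hop at exactly zero kinetic energy is accepted with
   velocities unchanged;
6. energy-based decoherence: non-active amplitudes are damped with
   $\tau_j = \frac{\hbar}{|E_j - E_a|}(1 + C/E_{\mathrm{kin}})$, with
   $C = 0.1$ hartree, the standard constant for this correction, and the
   active amplitude rescaled to restore the norm.  The kinetic energy of **all** modes enters; the
   alternative (a subset) is not specified anywhere and is not
   implemented.  At $E_{\mathrm{kin}} \le 0$ the correction is skipped
   for that step.

The initially selected MCH state is mapped at $t = 0$ to the diagonal
state of maximum overlap ($\arg\max_\alpha |U^{\mathrm{diag}}_{m\alpha}|$,
the least surprising contract).  Two conventions are offered for the
initial coefficient vector: the pure diagonal active state (`"diag"`,
ensemble default) or the selected MCH state expressed in the diagonal
basis (`"mch"`, a coherent superposition) — the latter is the right
choice when comparing electronic populations against exact quantum
references, which start from a pure spin state.

# Validation strategy and what a green test establishes

* Frozen nuclei: the propagation is exact; a two-level SOC model matches
  the closed-form Rabi oscillation to 1e-13.
* Prescribed nuclear path: the local-diabatization propagator matches
  direct Runge-Kutta integration of the time-dependent Schrödinger
  equation in the diabatic basis to about 1e-4 over 200 fs through a
  crossing (time-discretization level).
* Full ensembles: a two-mode model with one photoexcited singlet and two
  triplet acceptors (crossing seam displaced from the Franck-Condon
  region, weak constant SOC of 0.004 eV) is compared at $t = 100$ fs —
  the end of the quasi-irreversible transfer window — against a
  numerically exact wavepacket propagation in a harmonic-oscillator
  product basis.  Agreement is required within 3 sigma of the binomial
  Monte-Carlo error at 500 trajectories.

The window choice deserves honesty: beyond roughly 100 fs this toy (like
any few-mode quantum system) shows finite-size recurrences — coherent
back-transfer to the singlet — that no independent-trajectory method
reproduces, and the energy-based decoherence correction is nearly
inactive in small models (with few modes the kinetic energy is far below
$C = 0.1$ hartree, so $\tau_j$ is thousands of fs).  One-mode variants of
the toy disagree with the exact result at late times for exactly this
reason.  A green ensemble test therefore establishes that the coupled
nuclear-electronic machinery (forces, overlaps, propagator, hops,
rescaling) is implemented correctly in a regime where surface hopping is
valid — not that surface hopping reproduces exact quantum dynamics
everywhere.

# Analyses

**Populations** are offered in three representations (diagonal, MCH,
diabatic) with three estimators: active-count (fraction of trajectories,
mapped by $|A|^2$), coefficient ($|A c|^2$ averaged) and *mixed* — the
per-trajectory density matrix with the active state on the diagonal and
coefficient coherences off-diagonal, transformed then averaged.  The
mixed estimator is the default; wavefunction-aware surface populations
("partial Wigner transform" style) admit several recipes in the
surface-hopping literature, so all three candidates are exposed and the
default is documented as a choice.
The mixed estimator is not positive definite: small negative dips can
occur in small ensembles; dips beyond -1e-3 trigger a warning and the
series is clipped and renormalized so every slice stays an exact
partition of unity.

**Charge-transfer evolution** transforms the per-trajectory diabatic
coefficients with the CT-number table,
$\Omega^{el}_{AB}(t) = \sum_{nm} c^*_n c_m \Omega^{(n,m)}_{AB}$
(cross terms restricted to equal multiplicity and $M_S$), and aggregates
fragment pairs into the seven character classes.  Missing transition CT
numbers degrade gracefully to a diagonal-only evaluation with a prominent
warning.  Trajectory classes ("finishing in a CS state") use a
configurable CS-fraction threshold, default 50% at the final frame.

**Kinetics**: the total singlet population is fitted to
$S(t) = R_{\mathrm{fast}} e^{-t/\tau_{\mathrm{fast}}} +
(1 - R_{\mathrm{fast}}) e^{-t/\tau_{\mathrm{slow}}}$, the closed-form
solution of the hot/cold three-species scheme; the rate constants
$(\tau_1, \tau_2, \tau_c)$ follow from the printed algebraic identities
(verified to 1e-10 by a round-trip test), and uncertainties come from a
trajectory bootstrap.  Only the singlet population is fitted; the triplet
follows by normalization.

**Coherence descriptors** per mode over a window, relative to the
ground-state width $\sigma_0 = 1/\sqrt 2$: shiftEX (absolute time-mean of
the ensemble-mean coordinate over $\sigma_0$), cohEX (standard deviation
over time of the ensemble-mean trace divided by the trajectory-average of
each trajectory's own standard deviation over time, clipped to [0, 1])
and $\Delta\sigma$ (relative change of the time-averaged ensemble width).
These descriptors follow the normal-mode coherence-analysis idea from
the surface-hopping literature, whose operational definitions vary;
the definitions above are fixed conventions of this package,
chosen so that three null cases behave correctly (identical sinusoids
give cohEX = 1; random phases give cohEX below 0.1 at 200 trajectories;
a static ground-state Wigner ensemble gives shiftEX and $\Delta\sigma$
near 0).  Thresholds (defaults 0.25 / 0.3 / 0.15) are user-settable; a
mode is "important" when at least two descriptors exceed them.

# File formats and reproducibility

Models are stored in a canonical key-block text format (17 significant
digits, sorted record order) that round-trips byte-for-byte; a missing
SOC block reads as zero SOC with a warning.  Ensembles are archived as a
directory of plain-text TSV files with a versioned `manifest.json`
(schema v1); complex arrays are stored as paired real/imaginary columns.
A NetCDF backend was considered and deliberately not used: no NetCDF R
library is available in the supported environment, and the text format
was specified precisely so that no binary dependency is ever required to
read an archive.  Every CLI run writes a manifest (arguments, seeds,
package version, input hashes); ensembles derive one RNG stream per
trajectory from the master seed, so re-runs are bit-identical.

# Known limitations

* LVC surfaces are globally harmonic plus linear terms: torsions and
  other strongly anharmonic motions are not representable (nor are they
  meant to be), and excited-state curvature equals ground-state
  curvature by construction.
* Quantitative decay constants and charge-transfer compositions of a
  real chromophore require an ab-initio-derived LVC parameter set, which
  is outside the package's scope; the packaged fixture supplies reference
  vertical-excitation data, and everything else is validated against
  internal oracles.
* The mixed population estimator can dip slightly negative in small
  ensembles (see above).
* Memory: trajectories store per-step transforms for exact re-analysis;
  for large ensembles use `record_stride` to thin the stored steps.
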