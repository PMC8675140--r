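---
title: "Conditional wave function methods: models, solvers and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional wave function methods: models, solvers and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cwfdyn)
```

# The problem and the decomposition

`cwfdyn` treats small correlated electron–nuclear systems on real-space
grids, without Born–Oppenheimer surfaces as an input. The full wavefunction
$\Psi(x_1,\dots,x_n)$ of a few distinguishable degree-of-freedom blocks
(electrons, protons, relative coordinates; 1 or 2 spatial dimensions each)
is decomposed into *conditional wave functions* (CWFs): one-body slices
$\psi_i(x_i) \propto \Psi(x_i, \bar x_i^\alpha)$ taken at conditioning
points $x^\alpha$ drawn from the system's probability density. Exactly, a
slice obeys a one-body Schrödinger problem with a complex *kinetic
correlation potential* $\eta_i^\alpha(x_i)$ collecting the kinetic action of
all other coordinates; `kinetic_correlation_potential()` evaluates it on
oracle states and verifies the slice eigenproblem residual. The working
approximation drops $\eta$ at zeroth order around the conditioning point
(Hermitian limit), leaving the *conditional Hamiltonian*
$h_i^\alpha = K_i + W_i^\alpha(x_i)$ whose low eigenstates form a compact,
physically adapted one-body basis.

The variational machinery is a stochastic sum of products,
$$\Psi \approx \sum_{\alpha=1}^{N_c M} C_\alpha \prod_i \psi_i^\alpha(x_i),
\qquad \alpha = \lambda + N_c(\nu - 1),$$
with $N_c$ conditioning points and $M$ conditional excitations per point.
All matrix elements factorize over blocks: the overlap
$S_{\alpha\beta} = \prod_i \langle\psi_i^\alpha|\psi_i^\beta\rangle$, and the
Hamiltonian as one-body terms weighted by complementary overlap products
plus pair interactions by 2D quadrature (`overlap_matrix()`,
`hamiltonian_matrix()`, `operator_matrix()`).

Three solvers share this structure:

* **imaginary-time sta-ICWF** (`imag_time_solve()`): the projected flow
  $\dot C = -S^+(H - E(\tau)S)C$ with deflation for excited states — the
  package's eigensolver;
* **real-time sta-ICWF** (`sta_propagate()`): $i\dot C = S^+ H(t) C$ with a
  static basis, for linear response (delta kick) and driven dynamics;
* **dyn-ICWF** (`dyn_propagate()`): CWFs themselves propagate under their
  conditional Hamiltonians while the conditioning points move as Bohmian
  trajectories $\dot x_i^\alpha = \mathrm{Im}[\nabla_i\Psi/\Psi]/m_i$, and
  the coefficients follow $i\dot C = S^+(H - G)C$, where the coupling matrix
  $G$ (the conditional one-body generators acting on the ket CWFs) cancels
  all one-body content of $H$ — only genuine correlation drives $C$.

Everything is validated against *oracle* grid solutions: sparse
finite-difference eigensolves and FFT split-operator propagation of the full
tensor-product problem (`exact_eigenstates()`, `exact_propagate()`), plus a
multi-trajectory Ehrenfest baseline (`ehrenfest_baseline()`) representing
the mean-field methods the ICWF family is meant to improve on.

# Model systems

All quantities are in Hartree atomic units; times are additionally reported
in fs (1 au = 0.024189 fs).

* **1D H$_2$** (`build_h2_model()`): coordinates $(r_1, r_2, R)$ after
  center-of-mass separation; reduced masses $\mu_e = 2M/(2M+1)$,
  $\mu_n = M/2$ with $M = 1836$ (the conventional model-literature proton
  mass, exposed as an argument); soft-Coulomb interactions with
  $\epsilon_{ee} = 2$, $\epsilon_{en} = 1$ and bare $1/R$ nuclear repulsion
  (the $R$ grid excludes the origin). The dipole is $\mu_e = r_1 + r_2$.
* **1D electron–hydrogen scattering** (`build_scattering_model()`): two
  electrons, a fixed soft-Coulomb well of unit depth at $r = 10$, incident
  Gaussian packet of width parameter $\alpha = 0.1$ starting at $-10$
  (`scattering_initial_state()`), spatial singlet.
* **Shin–Metiu** (`build_shin_metiu_model()`): electron and proton in 1D
  between fixed ions at $\pm L/2$, $L = 19$; erf-screened electron
  interactions with screening lengths 5 (moving proton) and the printed
  pair (4, 3.1) for the fixed ions; bare proton–ion repulsion. The
  attachment of the two fixed-ion screening lengths is not uniquely fixed by
  the printed parameter list; the package resolves it so that the
  ground-state proton sits on the negative side ($\langle R\rangle \approx
  -2.6$), matching the stated sign of the equilibrium and the literature
  placement of the avoided crossing at $|R| \approx 1.9$.
* **Conical intersection** (`build_ci_model()`): a 2D electron and a 2D
  quantized proton with two fixed protons at $(\mp 0.4\sqrt3, 1.2)$. The
  printed parameters $a = 0.5$, $b = 10$, $R_0 = 1.5$ enter a smooth
  surrogate potential built in this package: soft-Coulomb electron–proton
  attraction $-1/\sqrt{d^2 + a}$ and Gaussian proton–proton cores
  $b\,e^{-d^2/R_0^2}$. Any radially symmetric pair potential makes the two
  lowest clamped-proton surfaces degenerate when the three protons are
  equilateral — i.e. a conical intersection at the origin — so the
  qualitative physics (a nuclear packet that falls toward the CI, splits,
  and self-interferes) does not hinge on the specific smooth form. All CI
  results in this package are therefore *self*-comparisons between dyn-ICWF
  and the package's own 4D oracle on identical grids. The initial nuclear
  packet $\chi \propto e^{-5|R - (0, 0.4)|^2}$ fixes the width scale printed
  with the model; the first excited clamped-proton state is phase-aligned
  over the nuclear grid outward from the packet center, which pushes the
  real-gauge branch cut to the far side of the CI.

# Sampling

Conditioning points are drawn exactly from grid densities: a cell is picked
with probability proportional to its density and the position jittered
uniformly inside the cell (`sample_configurations()`); given a seed the
ensemble is bitwise reproducible. Two modes exist: per-axis marginals (the
default guess mode) and the full joint density. The default *guess* density,
used when nothing better is available, is the product of per-block densities
of the conditional ground states with all other blocks clamped at the
classical potential minimum (`guess_density()`). When an oracle (or
previously converged) state is at hand its density is the better importance
sampler, and the bundled delta-kick example uses the oracle ground-state
joint density: correlated draws place configurations where the correlated
wavefunction actually lives, which matters visibly for the vibronic
manifold. For identical particles, `symmetrize_ensemble()` closes the
ensemble under label exchange so a spatially symmetric state is sampled
symmetrically. Imaginary-time runs keep the ensemble frozen; in dyn-ICWF
the points move with the probability flow instead of being resampled.

# Numerical choices

* **Grids.** Uniform tensor-product grids in bohr. Conditional Hamiltonians
  use 4th-order central finite differences so they are explicit sparse
  matrices for eigensolving; oracle propagation and the CWF propagation use
  FFT (spectral) kinetic steps. Default extents: H$_2$ electrons
  $[-18, 18]$, internuclear $R \in [0.3, 5.2]$; scattering $[-60, 90]$;
  Shin–Metiu $r \in [-25, 25]$, $R \in [-9, 9]$; CI model $\pm 5$
  (electron) and $\pm 3$ (proton) with 24 points per axis. The bundled
  examples run at desk scale (48–384 points per axis, $N_c$ between 16 and
  512) chosen so that each example finishes in minutes; every extent and
  count is a config knob and the defaults were checked by convergence scans.
* **Eigensolvers.** A Lanczos solver with full reorthogonalization
  (`lanczos_lowest()`) — the environment provides no sparse iterative
  eigensolver — switching automatically to shift-invert with a sparse LU
  (`lanczos_shift_invert()`) for one- and two-axis problems, where the
  potential minimum provides a free, safe lower shift; beyond $2\times10^6$
  grid points imaginary-time FFT propagation with deflation takes over
  (`imag_time_states()`).
* **Imaginary-time integration.** For a static basis the projected flow is
  linear, so the default integrator diagonalizes the Hermitian pencil
  $(H, S)$ restricted to the numerical range of $S$ and evaluates the flow
  (and its energy trace) in closed form; an explicit Euler stepper with
  renormalization and step halving integrates the same flow and is kept as
  a cross-check. Both deflate converged states by $S$-orthogonalization.
* **Pseudo-inverse.** $S$ is a Gram matrix of a stochastic basis and is
  routinely near-singular; $S^+$ uses an eigendecomposition with relative
  cutoff `rcond` (default 1e-8). The excited-state surface solver uses 1e-10:
  at compressed geometries the stochastic basis is strongly overcomplete and
  the default cutoff demonstrably discards physically useful directions
  (the excited surfaces improve monotonically as the cutoff is lowered
  until round-off takes over). The effective rank is reported and rank collapse
  warned about.
* **Real-time integration.** RK4 with midpoint field values for driven
  runs; for field-free runs (after a kick) the same linear equation is
  integrated exactly in the pencil eigenbasis (`method = "spectral"`), which
  removes time-stepping error at any output stride. The two paths agree to
  1e-6 on overlapping cases (tested).
* **dyn-ICWF stepping.** Strang ordering: half-step of every CWF under its
  conditional Hamiltonian (split-operator, exactly norm-preserving per CWF),
  Heun update of the trajectories with velocities from the midpoint CWFs and
  a refresh of the conditional potentials, second half-step, then RK4 on the
  coefficients with $S$, $G$ and the $H$-action rebuilt at the substep
  times. Each CWF is propagated in its energy gauge: the instantaneous
  conditional energy $\langle\psi_i^\alpha|h_i^\alpha|\psi_i^\alpha\rangle$
  is rotated out of the CWF and compensated in the coefficient equation
  ($G \to G - S\,e_\beta$), which removes the fast absolute-energy phases
  from all matrix elements. The reconstructed wavefunction is exactly gauge
  invariant, while the overlap-norm drift of the split scheme falls by more
  than two orders of magnitude at fixed step size. Trajectories reaching a grid edge are reflected (default) or
  clamped. The Bohmian quotient is clamped to zero where the reconstructed
  density falls below 1e-12 of its ensemble maximum. Default steps:
  $d\tau = 0.05$, $dt = 0.01$–0.4 depending on the masses involved.
* **Pair terms.** Interaction kernels are tabulated on the joint sub-grid.
  For static-basis matrix builds they enter through an SVD factorization
  evaluated in memory-bounded BLAS-3 batches; soft-Coulomb kernels on large
  grids are effectively full rank (the diagonal ridge), so the dyn-ICWF
  coefficient update never assembles the pair matrix at all — for two-block
  models the action of the pair Hamiltonian on $C$ is computed by
  reconstructing $\Psi_C$ on the joint grid, weighting by the kernel and
  contracting back (three small matrix products per evaluation).
* **Degeneracies and phases.** Conditional eigenvectors get a deterministic
  phase (first significant component real-positive) and exact degeneracies
  are ordered by $\langle x\rangle$, then $\langle x^2\rangle$, making bases
  reproducible across LAPACK backends.

# What the bundled examples show

* `bopes_h2`: electronic sta-ICWF at $(N_c, M) = (32, 5)$ against oracle
  clamped-nucleus diagonalization for the five lowest surfaces.
* `kick_h2`: the delta-kick (Yabana–Bertsch) dipole response at
  $(N_c, M) = (512, 3)$, its $S_2 \leftarrow S_0$ vibronic spectrum against
  the oracle, and the MTEF baseline whose peak spacing is visibly wrong.
  Convergence note: at this basis size the low vibronic lines sit within a
  frequency bin of the oracle while the deviation grows with energy, so the
  long-time dipole trace slowly dephases from the oracle; enlarging the
  basis systematically removes this (the trend from 256 to 512
  configurations is monotone), at a cost that grows quadratically in
  $N_c M$.
* `drive_h2`: a 20-cycle $\sin^2$ pulse at the vertical $S_0\to S_2$
  resonance ($E_0 = 0.005$), showing bond stretch and dipole resurgence.
* `scattering`: impact ionization at $p = 1.5$; the reduced electron
  density at $t = 0.85$ fs against the oracle, averaged over independent
  sampling realizations (the stochastic basis error averages down roughly
  as $1/\sqrt{N_{\rm real}}$).
* `shin_metiu`: a resonant $\sin^2(\pi t/20)$ pulse with $E_0 = 0.006$
  drives a passage through the avoided crossing; adiabatic populations
  $P_n(t)$ and the decoherence indicator are compared with the oracle and
  the MTEF baseline.
* `conical`: the nuclear packet traverses the CI and self-interferes; the
  reduced nuclear density snapshot is compared with the 4D oracle.

The population projector uses Born–Oppenheimer states tabulated on the
nuclear grid; the decoherence indicator implemented is the overlap of the
per-surface nuclear densities,
$D_{nm}(t) = \int dR\,|\chi_n|^2|\chi_m|^2$ with
$\chi_n = \langle\Phi^n|\Psi\rangle_{\rm elec}$ — the standard choice in the
decoherence literature: transiently large while a coherent superposition
crosses the coupling region, decaying to zero as the packets separate. It is
isolated in `decoherence_indicator()` so an alternative definition can be
swapped in.

# What the generator emulates — and what it does not

The synthetic study conditions are the four model systems above at desk
scale: soft-Coulomb interactions, one or two quantum nuclei, perfect
isolation, exactly known initial states. Passing tests show that the ICWF
machinery reproduces grid-exact correlated dynamics where mean-field fails —
they do not show anything about real molecules with many nuclear degrees of
freedom, fermionic antisymmetry (the ansatz here is a spatial product;
Slater-determinant CWFs would be an extension), spin, finite temperature, or
non-grid electronic structure. The oracle itself is limited to a few
dimensions; beyond that the method's accuracy must be argued by convergence
in $(N_c, M)$ rather than by comparison.

# Known limitations

* The overlap pencil becomes ill-conditioned as the stochastic basis grows;
  results depend mildly on `rcond` near rank collapse (reported, warned).
* Long-time sta-ICWF response dephases when the projected spectrum is not
  fully converged (see the `kick_h2` note); dyn-ICWF inherits trajectory
  noise at small $N_c$.
* MTEF sampling uses a Gaussian Wigner approximation matched to the nuclear
  marginal's mean and variance — adequate for near-Gaussian ground states,
  which is the regime in which the baseline is used here.
* The dyn-ICWF trajectory boundary handling (reflect/clamp) matters only
  when trajectories reach the grid edge; absorbing runs rely on the grid
  being large enough that edge trajectories carry negligible weight.
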