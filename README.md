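# cwfdyn

Grid-based quantum dynamics of correlated electron–nuclear model systems
with **conditional wave functions** (CWFs), in R.

## The problem

Solving the full time-(in)dependent Schrödinger equation of even a handful
of coupled electronic and nuclear degrees of freedom on a real-space grid
scales exponentially, while mean-field trajectory methods (Ehrenfest)
miss exactly the electron–nuclear correlation that drives vibronic spectra,
inelastic scattering and decoherence. `cwfdyn` implements a
multiconfigurational middle road for researchers studying nonadiabatic
dynamics on model Hamiltonians: the full wavefunction is expanded in a
stochastic sum of products of one-body **conditional wave functions** —
slices of the wavefunction at sampled conditioning points
$x^\alpha$ —

$$\Psi(x,t) \;\approx\; \sum_{\alpha=1}^{N_cM} C_\alpha(t)\,
\prod_i \psi_i^\alpha(x_i),$$

with variational complex coefficients obtained from the Dirac–Frenkel
principle through the overlap and Hamiltonian matrices
$S_{\alpha\beta}=\prod_i\langle\psi_i^\alpha|\psi_i^\beta\rangle$,
$H_{\alpha\beta}$ (pseudo-inverted overlap for the near-singular stochastic
basis). Three solvers share the machinery:

* **imaginary-time sta-ICWF** — ground and excited states by the projected
  flow $\dot C = -S^+(H - E(\tau)S)C$ with deflation;
* **real-time sta-ICWF** — $i\dot C = S^+H(t)C$ for delta-kick absorption
  spectra and laser-driven dynamics on a static conditional-eigenstate
  basis;
* **dyn-ICWF** — the CWFs themselves evolve under their conditional
  Hamiltonians along Bohmian trajectories
  $\dot x^\alpha_i = \mathrm{Im}[\nabla_i\Psi/\Psi]/m_i$, with
  $i\dot C = S^+(H-G)C$, for far-from-equilibrium problems (scattering,
  conical intersections).

Everything is checked against exact grid solutions (sparse Lanczos /
shift-invert eigensolves, FFT split-operator propagation) and against a
multi-trajectory Ehrenfest baseline. Four model systems ship with the
package: a 1D H₂ molecule (soft-Coulomb), 1D electron–hydrogen scattering,
the Shin–Metiu proton-coupled electron-transfer model, and a 2D+2D
conical-intersection model.

## Worked example

Ground and first-excited states of the 1D soft-Coulomb atom that serves as
the scattering target, and its lowest excitation energy:

```r
library(cwfdyn)
scat <- build_scattering_model()
atom <- model_system(
  data.frame(label = "r", dim = 1L, mass = 1, charge = -1),
  one_body = list(scat$one_body[[1]]), name = "atom")
g  <- system_grid(atom, list(grid_axis(-20, 40, 512)))
ed <- exact_eigenstates(atom, g, k = 2)
round(ed$energies, 5)
#> [1] -0.66978 -0.27489
round(diff(ed$energies), 4)
#> [1] 0.3949
```

The gap of 0.3949 hartree is the ≈ 0.4 au lowest excitation that separates
elastic from inelastic impact in the scattering example. A stochastic ICWF
eigensolve of a small correlated two-particle model against the same
oracle:

```r
m   <- model_system(
  data.frame(label = c("a", "b"), dim = 1L, mass = c(1, 2), charge = 0),
  one_body = list(function(X) 0.5 * X[,1]^2, function(X) X[,1]^2),
  pairs = list(list(i = 1L, j = 2L,
                    f = function(X1, X2) 0.8 / sqrt(1 + (X1[,1] - X2[,1])^2))))
gr  <- system_grid(m, list(grid_axis(-6, 6, 16), grid_axis(-5, 5, 16)))
ens <- sample_configurations(array(1, gr$n), gr, 8, seed = 3, mode = "joint")
bas <- conditional_eigenbasis(m, gr, ens, M = 2)
sol <- imag_time_solve(bas, m, k_states = 3)
round(sol$energies, 5)          # variational: each >= the exact value
#> [1] 1.64037 2.45000 2.61212
round(exact_eigenstates(m, gr, k = 3)$energies, 5)
#> [1] 1.64015 2.44969 2.61056
```

The six bundled experiments (`run_example()`, or the thin CLI in
`inst/cli/icwf-lab.R`) reproduce, at desk scale, Born–Oppenheimer surface
scans, the H₂ vibronic absorption spectrum with its mean-field failure,
strong-field driving, impact ionization, laser-driven proton-coupled
electron transfer with decoherence, and wavepacket interference behind a
conical intersection. The methods vignette
(`vignettes/cwf-methods.Rmd`) documents the models, solver choices,
tunable parameters and known limitations.

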