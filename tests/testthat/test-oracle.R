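test_that("eigensolver reproduces harmonic-oscillator and separable spectra", {
  m <- ho_model()
  g <- system_grid(m, list(grid_axis(-8, 8, 128)))
  ed <- exact_eigenstates(m, g, k = 4)
  expect_equal(ed$energies, c(0.5, 1.5, 2.5, 3.5), tolerance = 1e-4)
  # orthonormality
  V <- sapply(ed$states, function(s) as.vector(s$psi))
  Gm <- crossprod(V) * g$axes[[1]]$dx
  expect_lt(max(abs(Gm - diag(4))), 1e-8)
  # separable 2D model: energies are sums of 1D energies
  m2 <- sep_model()
  g2 <- system_grid(m2, list(grid_axis(-8, 8, 48), grid_axis(-8, 8, 48)))
  ed2 <- exact_eigenstates(m2, g2, k = 3)
  w1 <- 1; w2 <- sqrt(2 * 0.3 / 1.5)
  ref <- sort(as.vector(outer(w1 * (0:3 + 0.5), w2 * (0:3 + 0.5), "+")))[1:3]
  expect_equal(ed2$energies, ref, tolerance = 1e-3)
})

test_that("shift-invert and plain Lanczos agree", {
  m <- toy2_model()
  g <- toy2_grid(m, 20L)
  H <- hamiltonian_sparse(m, g)
  a <- lanczos_lowest(H, k = 3, n = nrow(H), tol = 1e-10)
  b <- lanczos_shift_invert(H, k = 3, tol = 1e-10)
  expect_equal(a$values, b$values, tolerance = 1e-9)
})

test_that("soft-Coulomb target atom has its lowest excitation near 0.4 hartree", {
  m <- build_scattering_model()
  m1 <- model_system(data.frame(label = "r", dim = 1L, mass = 1, charge = -1),
                     one_body = list(m$one_body[[1]]), name = "atom")
  g <- system_grid(m1, list(grid_axis(-20, 40, 512)))
  ed <- exact_eigenstates(m1, g, k = 2)
  expect_lt(abs((ed$energies[2] - ed$energies[1]) - 0.4), 0.01)
})

test_that("split-operator propagation: stationary states stay, norms hold", {
  m <- ho_model()
  g <- system_grid(m, list(grid_axis(-8, 8, 128)))
  ed <- exact_eigenstates(m, g, k = 1)
  run <- exact_propagate(m, g, ed$states[[1]], dt = 0.05, Tmax = 10,
                         stride = 20, autocorr = TRUE)
  expect_gt(min(run$series$autocorr), 1 - 1e-6)
  expect_lt(max(abs(run$series$norm - 1)), 1e-8)
})

test_that("free Gaussian spreads at the analytic rate", {
  m <- free_model()
  g <- system_grid(m, list(grid_axis(-40, 40, 256)))
  wf <- grid_wavefunction(g, exp(-g$axes[[1]]$x^2 / 4)) # sigma_x^2 = 1
  x2op <- list(x2 = function(p, gr) {
    d <- Mod(p)^2
    sum(gr$axes[[1]]$x^2 * d) / sum(d)
  })
  run <- exact_propagate(m, g, wf, dt = 0.02, Tmax = 5, stride = 25,
                         extra = x2op)
  tt <- run$series$time_au
  v0 <- run$series$x2[1]
  expect_lt(max(abs(run$series$x2 - (v0 + tt^2 / (4 * v0)))), 1e-4)
})

test_that("a kicked harmonic oscillator rings at exactly its own frequency", {
  m <- ho_model()
  g <- system_grid(m, list(grid_axis(-8, 8, 128)))
  ed <- exact_eigenstates(m, g, k = 1)
  kicked <- grid_wavefunction(g, ed$states[[1]]$psi * exp(1i * 0.02 * g$axes[[1]]$x),
                              normalize = FALSE)
  run <- exact_propagate(m, g, kicked, dt = 0.05, Tmax = 150, stride = 2)
  sp <- absorption_spectrum(run$series, kappa = 0.02)
  pk <- spectrum_peaks(sp, threshold = 0.5)
  expect_equal(nrow(pk), 1L)
  dbin <- sp$omega_au[2] - sp$omega_au[1]
  expect_lt(abs(pk$omega_au[1] - 1), dbin + 1e-9)
  # sign convention: the absorption line is a positive peak that dominates
  # any (window-leakage) negative side structure
  expect_gt(max(sp$strength), abs(min(sp$strength)))
})

test_that("BOPES surfaces are ordered and the H2 vertical gap matches the carrier frequency", {
  model <- build_h2_model()
  sub <- electronic_submodel(model, 3L)
  ge <- system_grid(sub$model, list(grid_axis(-16, 16, 72), grid_axis(-16, 16, 72)))
  Rs <- seq(0.6, 5, length.out = 12)
  bt <- compute_bopes(model, ge, Rs, 3L, k = 3)
  expect_true(all(diff(t(bt$surfaces)) >= -1e-10)) # ordered at every R
  gap <- spline(Rs, bt$surfaces[, 3] - bt$surfaces[, 1], xout = 2.0)$y
  expect_equal(gap, 0.403, tolerance = 0.02)
})

test_that("nuclear motion on the ground surface recovers most of the full 3D energy", {
  model <- build_h2_model()
  grid <- h2_small_grid(model)
  full <- imag_time_states(model, grid, k = 1, tol = 1e-9)
  sub <- electronic_submodel(model, 3L)
  ge <- system_grid(sub$model, list(grid$axes[[1]], grid$axes[[2]]))
  Rax <- grid$axes[[3]]
  bt <- compute_bopes(model, ge, Rax$x, 3L, k = 1)
  ns <- curve_eigensolve(Rax, bt$surfaces[, 1], model$params$mu_n, k = 1)
  # Born-Oppenheimer energy agrees with the full solve to < 5e-3 hartree
  expect_lt(abs(ns$values[1] - full$energies[1]), 5e-3)
})

test_that("conditional slices factor product states and reassemble rank-1 states", {
  m <- sep_model()
  g <- system_grid(m, list(grid_axis(-6, 6, 32), grid_axis(-6, 6, 32)))
  f <- exp(-(g$axes[[1]]$x - 0.5)^2)
  h <- exp(-(g$axes[[2]]$x + 0.3)^2 / 2)
  wf <- grid_wavefunction(g, outer(f, h))
  sl <- conditional_slice(wf, 1L, c(NA, 1.0))
  iy <- which.min(abs(g$axes[[2]]$x - 1.0))
  fn <- f / sqrt(sum(f^2) * g$axes[[1]]$dx)
  expect_lt(max(abs(Mod(as.vector(sl$normalized)) - fn)), 1e-10)
  # slice weight of a product state: |h(x2_bar)| / ||h||
  expect_equal(sl$weight, abs(h[iy]) / sqrt(sum(h^2) * g$axes[[2]]$dx),
               tolerance = 1e-10)
  # rank-1 reassembly: slice along each axis at the same point rebuilds the state
  s1 <- conditional_slice(wf, 1L, c(NA, 0.7))
  s2 <- conditional_slice(wf, 2L, c(0.2, NA))
  rec <- outer(as.vector(s1$normalized), as.vector(s2$normalized))
  ov <- abs(sum(Conj(rec) * wf$psi) * grid_dvol(g))
  expect_equal(ov, 1, tolerance = 1e-10)
})

test_that("slice weights integrate to one over the sampled ensemble on average", {
  m <- toy2_model()
  g <- toy2_grid(m, 24L)
  ed <- exact_eigenstates(m, g, k = 1)
  wf <- ed$states[[1]]
  ens <- sample_configurations(wf, g, 400, seed = 9, mode = "joint")
  # E_{x2 ~ |psi|^2 marginal}[ w(x2)^2 / p(x2) ] = 1 by construction;
  # Monte-Carlo check through the importance-weighted average
  w2 <- vapply(seq_len(400), function(a) {
    sl <- conditional_slice(wf, 1L, ens$configs[a, ])
    sl$weight^2
  }, numeric(1))
  rd <- reduced_density(wf, 2L)
  iy <- vapply(seq_len(400), function(a)
    which.min(abs(g$axes[[2]]$x - ens$configs[a, 2])), integer(1))
  p <- rd$density[iy] # density per unit length
  est <- mean(w2 / p)
  expect_equal(est, 1, tolerance = 0.05)
})

test_that("kinetic correlation potential: constant for separable states, solves the slice problem", {
  m <- sep_model()
  g <- system_grid(m, list(grid_axis(-7, 7, 48), grid_axis(-7, 7, 48)))
  ed <- exact_eigenstates(m, g, k = 1, tol = 1e-11)
  r <- kinetic_correlation_potential(m, g, ed$states[[1]], ed$energies[1],
                                     1L, c(NA, 0.4))
  eta <- r$eta[r$mask]
  expect_lt(max(Mod(eta - mean(eta))), 1e-5) # constant up to the energy offset
  expect_lt(r$residual, 1e-6)
  # correlated model: eta varies along the slice
  mt <- toy2_model(coupling = 1.5)
  gt <- system_grid(mt, list(grid_axis(-6, 6, 48), grid_axis(-5, 5, 48)))
  edt <- exact_eigenstates(mt, gt, k = 1, tol = 1e-11)
  rt <- kinetic_correlation_potential(mt, gt, edt$states[[1]], edt$energies[1],
                                      1L, c(NA, 0.8))
  etat <- rt$eta[rt$mask]
  expect_gt(max(Re(etat)) - min(Re(etat)), 1e-3)
  expect_lt(rt$residual, 1e-6)
})

test_that("Ehrenfest is exact for an uncoupled harmonic nuclear coordinate", {
  # 'molecule': one light electron + one harmonic heavy coordinate, no pair
  m <- model_system(
    data.frame(label = c("r", "R"), dim = 1L, mass = c(1, 100), charge = c(-1, 1)),
    one_body = list(function(X) 0.5 * X[, 1]^2,
                    function(X) 0.5 * 100 * 0.05^2 * X[, 1]^2),
    dipole = list(1, 0), name = "hoho")
  g <- system_grid(m, list(grid_axis(-6, 6, 32), grid_axis(-2, 2, 32)))
  sub <- electronic_submodel(m, 2L)
  ge <- system_grid(sub$model, list(g$axes[[1]]))
  # displaced nuclear Gaussian: <R>(t) = R0 cos(w t) quantum = classical
  R0 <- 0.4; w <- 0.05
  mt <- ehrenfest_baseline(m, ge, 2L, n_traj = 24, dt = 0.5, Tmax = 60,
                           seed = 2, nuclear_stats = list(mean = R0, var = 0.01),
                           stride = 10)
  tt <- mt$series$time_au
  # ensemble average follows the classical/quantum harmonic motion; the
  # Monte-Carlo tolerance includes both the position spread and the (much
  # larger, minimal-uncertainty) momentum spread sigma_P = 1/(2 sigma_R)
  sigR <- 0.1; sigP <- 1 / (2 * sigR)
  se <- sqrt(sigR^2 + (sigP / (100 * w))^2) / sqrt(24)
  expect_lt(max(abs(mt$series$R - R0 * cos(w * tt))), 4 * se)
})
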