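# deterministic small basis shared by several blocks below
make_toy_basis <- function(Nc = 8L, M = 2L, n = 16L, seed = 3L) {
  m <- toy2_model()
  g <- toy2_grid(m, n)
  ens <- sample_configurations(array(1, g$n), g, Nc, seed = seed, mode = "joint")
  list(model = m, grid = g, ens = ens,
       basis = conditional_eigenbasis(m, g, ens, M = M))
}

test_that("conditional Hamiltonians clamp the partner coordinates", {
  m <- toy2_model()
  g <- toy2_grid(m, 24L)
  h <- conditional_hamiltonian(m, g, 1L, c(0, 1.5))
  expect_lt(max(abs(h - Matrix::t(h))), 1e-12)
  W <- conditional_potential_values(m, g, 1L, c(0, 1.5))
  x <- g$axes[[1]]$x
  expect_equal(W, 0.5 * x^2 + 0.8 / sqrt(1 + (x - 1.5)^2), tolerance = 1e-12)
  # non-interacting model: independent of the clamp
  ms <- sep_model()
  gs <- system_grid(ms, list(grid_axis(-6, 6, 24), grid_axis(-6, 6, 24)))
  W1 <- conditional_potential_values(ms, gs, 1L, c(0, -2))
  W2 <- conditional_potential_values(ms, gs, 1L, c(0, 3))
  expect_equal(W1, W2)
})

test_that("conditional eigenbasis has the right size, nodes and deterministic phase", {
  tb <- make_toy_basis(Nc = 5L, M = 3L, n = 32L)
  expect_equal(ncol(tb$basis$psis[[1]]), 15L) # Nc * M
  expect_equal(nrow(tb$basis$prov), 15L)
  # nodal structure of the conditional excitations (harmonic-like wells):
  # nu-th state has nu-1 sign changes
  for (nu in 1:3) {
    col <- 1L + 5L * (nu - 1L)
    v <- Re(tb$basis$psis[[1]][, col])
    v[abs(v) < 1e-6 * max(abs(v))] <- 0
    sgn <- sign(v[v != 0])
    expect_equal(sum(diff(sgn) != 0), nu - 1L)
  }
  # rebuilt basis is identical (deterministic phases/ordering)
  bas2 <- conditional_eigenbasis(tb$model, tb$grid, tb$ens, M = 3L)
  expect_equal(tb$basis$psis, bas2$psis, tolerance = 1e-12)
})

test_that("overlap matrix is a Hermitian PSD Gram matrix with unit diagonal", {
  tb <- make_toy_basis()
  S <- overlap_matrix(tb$basis)
  expect_lt(max(abs(diag(S) - 1)), 1e-12)
  expect_lt(max(abs(S - Conj(t(S)))), 1e-12)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("factorized S and H equal brute-force tensor contraction", {
  tb <- make_toy_basis()
  S <- overlap_matrix(tb$basis)
  H <- hamiltonian_matrix(tb$basis, tb$model)
  expect_lt(max(abs(H - Conj(t(H)))), 1e-10)
  Hfull <- hamiltonian_sparse(tb$model, tb$grid)
  dv <- grid_dvol(tb$grid)
  Ncm <- ncol(tb$basis$psis[[1]])
  Psis <- sapply(seq_len(Ncm), function(a)
    as.vector(outer(tb$basis$psis[[1]][, a], tb$basis$psis[[2]][, a])))
  Sb <- crossprod(Conj(Psis), Psis) * dv
  Hb <- crossprod(Conj(Psis), cwfdyn:::sp_cmult(Hfull, Psis)) * dv
  expect_lt(max(abs(S - Sb)), 1e-10)
  expect_lt(max(abs(H - Hb)), 1e-10)
  # the pair-term matvec used by the dyn propagator agrees with the full H
  C <- complex(real = rnorm(Ncm), imaginary = rnorm(Ncm))
  ob <- lapply(1:2, function(i)
    tb$model$one_body[[i]](cwfdyn:::block_coords(tb$grid, i)))
  H1 <- operator_matrix(tb$basis, one_body = ob, kinetic = TRUE)
  pv <- cwfdyn:::pair_hamiltonian_matvec(tb$basis, C)
  expect_lt(max(Mod(H1 %*% C + pv - H %*% C)), 1e-9)
})

test_that("single-configuration H is the Rayleigh energy of the product state", {
  m <- toy2_model()
  g <- toy2_grid(m, 20L)
  bas <- conditional_eigenbasis(m, g, matrix(c(0.3, -0.2), 1, 2), M = 1L)
  H <- hamiltonian_matrix(bas, m)
  Hfull <- hamiltonian_sparse(m, g)
  prod_state <- as.vector(outer(bas$psis[[1]][, 1], bas$psis[[2]][, 1]))
  ray <- sum(Conj(prod_state) * cwfdyn:::sp_cmult(Hfull, matrix(prod_state))) *
    grid_dvol(g)
  expect_equal(as.complex(H[1, 1]), as.complex(ray), tolerance = 1e-10)
})

test_that("coupling matrix cancels one-body content against H", {
  # separable model: H - G has no one-body content left, so (H-G)C = 0
  m <- sep_model()
  g <- system_grid(m, list(grid_axis(-6, 6, 24), grid_axis(-6, 6, 24)))
  ens <- sample_configurations(array(1, g$n), g, 6L, seed = 2, mode = "joint")
  bas <- conditional_eigenbasis(m, g, ens, M = 1L)
  H <- hamiltonian_matrix(bas, m)
  G <- coupling_matrix(bas, m, bas$traj)
  expect_lt(max(abs(H - G)), 1e-10)
  expect_true(all(is.finite(Mod(G))))
  # interacting model: G stays finite but differs from H by the pair terms
  tb <- make_toy_basis()
  G2 <- coupling_matrix(tb$basis, tb$model, tb$basis$traj)
  expect_true(all(is.finite(Mod(G2))))
})

test_that("pseudo-inverse application: identity, rank-1 projection, reported rank", {
  S <- diag(4) + 0i
  r <- pseudo_inverse_apply(S, c(1, 2, 3, 4) + 0i)
  expect_equal(r$x, c(1, 2, 3, 4) + 0i)
  expect_equal(r$rank, 4L)
  u <- c(1, 1, 0, 0) / sqrt(2)
  S1 <- outer(u, u) + 0i
  r1 <- pseudo_inverse_apply(S1, c(1, 0, 0, 1) + 0i)
  expect_equal(r1$rank, 1L)
  # output lives in the rank-1 subspace
  expect_lt(max(Mod(r1$x - u * sum(u * r1$x) / sum(u * u))), 1e-12)
})

test_that("imaginary-time solve is variational, ordered and duplicate-invariant", {
  tb <- make_toy_basis(Nc = 6L, M = 2L, n = 16L, seed = 8L)
  or <- exact_eigenstates(tb$model, tb$grid, k = 3)
  sol <- suppressWarnings(imag_time_solve(tb$basis, tb$model, k_states = 3))
  expect_true(all(diff(sol$energies) >= -1e-10))
  expect_true(all(sol$energies >= or$energies - 1e-8))
  expect_true(all(vapply(sol$traces,
                         function(tr) all(diff(tr$energy) <= 1e-9), logical(1))))
  # well-conditioned basis: duplicating a configuration changes nothing
  m1 <- toy2_model()
  g1 <- toy2_grid(m1, 16L)
  X <- matrix(c(0.5, -0.4, -1.1, 0.8, 0.2, 1.4), 3, 2)
  b1 <- conditional_eigenbasis(m1, g1, X, M = 1L)
  s1 <- imag_time_solve(b1, m1, k_states = 1)
  b2 <- conditional_eigenbasis(m1, g1, X[c(1, 2, 3, 1), ], M = 1L)
  s2 <- suppressWarnings(imag_time_solve(b2, m1, k_states = 1))
  expect_lt(abs(s1$energies[1] - s2$energies[1]), 1e-8)
})

test_that("exact and Euler imaginary-time integrators agree on the ground state", {
  m <- toy2_model()
  g <- toy2_grid(m, 16L)
  X <- matrix(c(0.5, -0.6, -1.0, 0.9, 0.1, -1.3, 1.2, 0.4), 4, 2)
  bas <- conditional_eigenbasis(m, g, X, M = 2L)
  ex <- imag_time_solve(bas, m, k_states = 1)
  eu <- imag_time_solve(bas, m, k_states = 1, integrator = "euler", tol = 1e-12)
  expect_lt(abs(ex$energies[1] - eu$energies[1]), 1e-7)
})

test_that("basis spanning the exact ground state recovers the oracle energy", {
  # complete-basis limit on a small two-block grid
  m <- toy2_model()
  g <- toy2_grid(m, 16L)
  or <- exact_eigenstates(m, g, k = 1, tol = 1e-11)
  ens <- sample_configurations(array(1, g$n), g, 16L, seed = 5, mode = "joint")
  bas <- conditional_eigenbasis(m, g, ens, M = 16L)
  sol <- suppressWarnings(imag_time_solve(bas, m, k_states = 1, rcond = 1e-10))
  expect_lt(abs(sol$energies[1] - or$energies[1]), 1e-6)
})

test_that("sta real-time propagation conserves the overlap norm and phases eigenvectors", {
  tb <- make_toy_basis(Nc = 6L, M = 2L, n = 16L)
  sol <- suppressWarnings(imag_time_solve(tb$basis, tb$model, k_states = 2))
  st <- icwf_state(tb$basis, tb$model, sol$coefficients[[1]],
                   S = sol$S, H = sol$H)
  C0 <- st$C
  n0 <- Re(sum(Conj(C0) * (st$S %*% C0)))
  for (s in 1:1000) st <- sta_real_time_step(st, 0.01)
  nT <- Re(sum(Conj(st$C) * (st$S %*% st$C)))
  expect_lt(abs(nT - n0), 1e-8)
  # projected eigenvector only acquires a phase
  ov <- Mod(sum(Conj(st$C) * (st$S %*% C0))) / n0
  expect_equal(ov, 1, tolerance = 1e-7)
})

test_that("rk4 and spectral real-time paths agree after a kick", {
  tb <- make_toy_basis(Nc = 6L, M = 2L, n = 16L)
  sol <- suppressWarnings(imag_time_solve(tb$basis, tb$model))
  mk <- function() {
    st <- icwf_state(tb$basis, tb$model, sol$coefficients[[1]],
                     S = sol$S, H = sol$H)
    kick_state(st, 0.05)
  }
  a <- sta_propagate(mk(), dt = 0.01, Tmax = 8, stride = 20)
  b <- sta_propagate(mk(), dt = 0.2, Tmax = 8, stride = 1, method = "spectral")
  expect_equal(a$series$mu, b$series$mu, tolerance = 1e-6)
})

test_that("Bohmian velocities: plane-wave momentum, zero for real states, spreading packet", {
  m <- sep_model()
  g <- system_grid(m, list(grid_axis(-10, 10, 96), grid_axis(-7, 7, 48)))
  x1 <- g$axes[[1]]$x; x2 <- g$axes[[2]]$x
  pw <- grid_wavefunction(g, outer(exp(1i * 0.7 * x1), exp(-x2^2 / 2)))
  bw <- slice_basis(m, g, pw, matrix(c(0.3, 0.1), 1, 2))
  v <- bohmian_velocities(bw, c(1 + 0i), matrix(c(0.33, 0.11), 1, 2))
  expect_equal(v[1, 1], 0.7, tolerance = 1e-3)
  expect_lt(abs(v[1, 2]), 1e-10)
  # real stationary state: zero velocity field
  rs <- grid_wavefunction(g, outer(exp(-x1^2 / 2), exp(-x2^2 / 2)))
  br <- slice_basis(m, g, rs, matrix(c(0.5, -0.3), 1, 2))
  vr <- bohmian_velocities(br, c(1 + 0i), matrix(c(0.2, 0.4), 1, 2))
  expect_lt(max(abs(vr)), 1e-10)
})

test_that("free-Gaussian trajectory ensemble spreads with the density", {
  mf <- model_system(
    data.frame(label = c("x", "y"), dim = 1L, mass = c(1, 1), charge = 0),
    one_body = list(function(X) 0 * X[, 1], function(X) 0.5 * X[, 1]^2),
    name = "free+ho")
  g <- system_grid(mf, list(grid_axis(-30, 30, 128), grid_axis(-6, 6, 32)))
  x1 <- g$axes[[1]]$x; x2 <- g$axes[[2]]$x
  wf0 <- grid_wavefunction(g, outer(exp(-x1^2 / 4), exp(-x2^2 / 2)))
  ens <- sample_configurations(wf0, g, 64L, seed = 12, mode = "joint")
  bas <- slice_basis(mf, g, wf0, ens)
  fit <- icwf_fit_coefficients(bas, wf0)
  st <- dyn_state(bas, mf, fit$C)
  out <- dyn_propagate(st, dt = 0.05, Tmax = 5, stride = 100)
  # trajectory variance tracks the analytic |psi|^2 variance sigma^2(t)
  v_emp <- var(out$state$traj[, 1])
  v_ref <- 1 + 5^2 / 4 # sigma0^2 = 1, m = 1
  se <- v_ref * sqrt(2 / 63)
  expect_lt(abs(v_emp - v_ref), 3 * se)
})

test_that("dyn-ICWF keeps eigenstates stationary and its norm drift small", {
  tb <- make_toy_basis(Nc = 8L, M = 2L, n = 16L, seed = 21L)
  sol <- suppressWarnings(imag_time_solve(tb$basis, tb$model))
  st <- dyn_state(tb$basis, tb$model, sol$coefficients[[1]])
  out <- dyn_propagate(st, dt = 0.001, Tmax = 1, stride = 100)
  expect_lt(max(abs(out$series$x1 - out$series$x1[1])), 1e-3)
  expect_lt(max(abs(out$series$x2 - out$series$x2[1])), 1e-3)
  drift <- max(abs(out$series$norm^2 - out$series$norm[1]^2))
  expect_lt(drift, 1e-5)
})

test_that("dyn-ICWF is exact for separable dynamics with a single configuration", {
  m <- sep_model()
  g <- system_grid(m, list(grid_axis(-7, 7, 48), grid_axis(-7, 7, 48)))
  x1 <- g$axes[[1]]$x; x2 <- g$axes[[2]]$x
  wf0 <- grid_wavefunction(g, outer(exp(-(x1 - 1)^2 / 2), exp(-(x2 + 0.8)^2 / 2)))
  bas <- slice_basis(m, g, wf0, matrix(c(1, -0.8), 1, 2))
  fit <- icwf_fit_coefficients(bas, wf0)
  expect_equal(fit$fidelity, 1, tolerance = 1e-10)
  st <- dyn_state(bas, m, fit$C)
  out <- dyn_propagate(st, dt = 0.0025, Tmax = 1.5, stride = 100)
  orr <- exact_propagate(m, g, wf0, dt = 0.0025, Tmax = 1.5, stride = 100)
  wrec <- reconstruct_wavefunction(out$state$basis, out$state$C)
  pr <- Mod(wrec$psi)^2; pr <- pr / (sum(pr) * grid_dvol(g))
  po <- Mod(orr$psi$psi)^2; po <- po / (sum(po) * grid_dvol(g))
  expect_lt(max(abs(pr - po)) * grid_dvol(g), 1e-6)
})

test_that("seeded pipelines are bitwise reproducible end to end", {
  run_once <- function() {
    m <- toy2_model()
    g <- toy2_grid(m, 16L)
    ens <- sample_configurations(array(1, g$n), g, 6L, seed = 17L, mode = "joint")
    bas <- conditional_eigenbasis(m, g, ens, M = 2L)
    sol <- suppressWarnings(imag_time_solve(bas, m))
    st <- dyn_state(bas, m, sol$coefficients[[1]])
    out <- dyn_propagate(st, dt = 0.05, Tmax = 0.5)
    list(E = sol$energies, C = out$state$C, traj = out$state$traj)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$E, b$E)
  expect_identical(a$C, b$C)
  expect_identical(a$traj, b$traj)
})
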