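test_that("expectation values: identity, symmetric positions, ICWF vs brute force", {
  tb_model <- toy2_model()
  g <- toy2_grid(tb_model, 16L)
  ens <- sample_configurations(array(1, g$n), g, 6L, seed = 13L, mode = "joint")
  bas <- conditional_eigenbasis(tb_model, g, ens, M = 2L)
  sol <- suppressWarnings(imag_time_solve(bas, tb_model, k_states = 1))
  st <- icwf_state(bas, tb_model, sol$coefficients[[1]], S = sol$S, H = sol$H)
  id_op <- operator_descriptor(one_body = list(function(X) rep(1, nrow(X)), NULL))
  expect_equal(expectation(st, id_op), 1, tolerance = 1e-10)
  # ICWF expectation equals brute-force contraction on the full grid
  op <- operator_descriptor(
    one_body = list(function(X) X[, 1], function(X) X[, 1]^2),
    pairs = list(list(i = 1L, j = 2L,
                      f = function(A, B) cos(A[, 1]) * exp(-(B[, 1])^2))))
  got <- expectation(st, op)
  wf <- reconstruct_wavefunction(bas, st$C)
  ref <- expectation(wf, op)
  expect_equal(got, ref, tolerance = 1e-10)
  # a symmetric grid state has <x> at its center of symmetry
  mh <- ho_model()
  gh <- system_grid(mh, list(grid_axis(-8, 8, 128)))
  wfh <- grid_wavefunction(gh, exp(-(gh$axes[[1]]$x - 0.5)^2))
  xop <- operator_descriptor(one_body = list(function(X) X[, 1]))
  expect_equal(expectation(wfh, xop), 0.5, tolerance = 1e-9)
})

test_that("reduced densities: product factors, particle-count convention, ICWF agreement", {
  m <- sep_model()
  g <- system_grid(m, list(grid_axis(-6, 6, 32), grid_axis(-6, 6, 32)))
  x1 <- g$axes[[1]]$x; x2 <- g$axes[[2]]$x
  f <- exp(-(x1 - 1)^2); h <- exp(-x2^2 / 2)
  wf <- grid_wavefunction(g, outer(f, h))
  rd <- reduced_density(wf, 1L)
  ref <- f^2 / (sum(f^2) * g$axes[[1]]$dx)
  expect_lt(max(abs(rd$density - ref)), 1e-10)
  # two-electron convention: integrates to 2
  rd2 <- reduced_density(wf, 1L, particles = 2)
  expect_equal(sum(rd2$density) * g$axes[[1]]$dx, 2, tolerance = 1e-12)
  # ICWF marginal equals the grid marginal when the basis spans the state
  ens <- sample_configurations(wf, g, 10L, seed = 2, mode = "joint")
  bas <- slice_basis(m, g, wf, ens)
  fit <- icwf_fit_coefficients(bas, wf)
  st <- dyn_state(bas, m, fit$C)
  rdi <- reduced_density(st, 1L)
  expect_lt(sum(abs(rdi$density - rd$density)) * g$axes[[1]]$dx, 1e-8)
})

test_that("spectra: single known line, zero response, mirror convention", {
  tt <- seq(0, 400, by = 0.2)
  w0 <- 0.35
  ser <- data.frame(time_au = tt, mu = 0.01 * sin(w0 * tt))
  sp <- absorption_spectrum(ser, kappa = 0.01, mask = "none")
  pk <- spectrum_peaks(sp, threshold = 0.5)
  dbin <- sp$omega_au[2] - sp$omega_au[1]
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$omega_au - w0), dbin)
  # null response -> null spectrum
  sp0 <- absorption_spectrum(data.frame(time_au = tt, mu = rep(2, length(tt))),
                             kappa = 0.01)
  expect_true(all(abs(sp0$strength) < 1e-12))
  # time-reversed dipole flips the spectrum sign
  ser_rev <- data.frame(time_au = tt, mu = rev(ser$mu) - ser$mu[length(tt)] + ser$mu[1])
  sp_rev <- absorption_spectrum(
    data.frame(time_au = tt, mu = -0.01 * sin(w0 * tt)), kappa = 0.01, mask = "none")
  expect_equal(sp_rev$strength, -sp$strength, tolerance = 1e-10)
  expect_error(absorption_spectrum(data.frame(time_au = tt^1.1, mu = tt), 0.01),
               "non-uniform")
})

test_that("adiabatic populations and decoherence match hand-built superpositions", {
  sm <- build_shin_metiu_model()
  g <- system_grid(sm, list(grid_axis(-25, 25, 96), grid_axis(-8, 8, 48)))
  sub <- electronic_submodel(sm, 2L)
  ge <- system_grid(sub$model, list(g$axes[[1]]))
  bt <- compute_bopes(sm, ge, g$axes[[2]]$x, 2L, k = 2, keep_states = TRUE)
  R <- g$axes[[2]]$x
  # pure surface-1 product state
  chi <- exp(-(R + 2)^2)
  psi1 <- sapply(seq_along(R), function(r) bt$states[[r]][, 1] * chi[r])
  wf1 <- grid_wavefunction(g, psi1)
  ap <- adiabatic_populations(wf1, bt, sm, 2)
  expect_equal(ap$P[1], 1, tolerance = 1e-8)
  expect_lt(ap$P[2], 1e-8)
  expect_lt(decoherence_indicator(wf1, bt, sm), 1e-10)
  expect_lt(sum(ap$P), 1 + 1e-8)
  # equal-weight fully overlapping packets: D = int (rho/2)^2 * ...
  chi_n <- chi / sqrt(sum(chi^2) * g$axes[[2]]$dx)
  psi_mix <- sapply(seq_along(R), function(r)
    (bt$states[[r]][, 1] + bt$states[[r]][, 2]) / sqrt(2) * chi_n[r])
  wfm <- grid_wavefunction(g, psi_mix, normalize = FALSE)
  apm <- adiabatic_populations(wfm, bt, sm, 2)
  expect_equal(apm$P, c(0.5, 0.5), tolerance = 1e-8)
  D <- decoherence_indicator(wfm, bt, sm)
  Dref <- sum((chi_n^2 / 2)^2) * g$axes[[2]]$dx
  expect_equal(D, Dref, tolerance = 1e-8)
  # disjoint packets on the two surfaces: decohered, D = 0
  chiL <- exp(-(R + 4)^2 * 4); chiR <- exp(-(R - 4)^2 * 4)
  psi_d <- sapply(seq_along(R), function(r)
    bt$states[[r]][, 1] * chiL[r] + bt$states[[r]][, 2] * chiR[r])
  wfd <- grid_wavefunction(g, psi_d)
  expect_lt(decoherence_indicator(wfd, bt, sm), 1e-12)
})

test_that("wavefunction checkpoints survive a save/load round trip", {
  m <- toy2_model()
  g <- toy2_grid(m, 16L)
  ed <- exact_eigenstates(m, g, k = 1)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ed$states[[1]], path, meta = list(model = "toy2"))
  wf2 <- load_checkpoint(path)
  expect_equal(wf2$psi, ed$states[[1]]$psi, tolerance = 1e-14)
  expect_equal(wf2$grid$n, g$n)
  unlink(path)
})
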