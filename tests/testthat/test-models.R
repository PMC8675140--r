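test_that("soft-Coulomb kernels reproduce their closed-form special values", {
  expect_equal(soft_coulomb(0, 2, 1), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(soft_coulomb(0, 1, -1), -1)
  # erf-screened Coulomb: finite at coincidence, bare Coulomb far away
  expect_equal(erf_coulomb(0, 3.1), 2 / (sqrt(pi) * 3.1), tolerance = 1e-12)
  expect_equal(erf_coulomb(100, 2), 1 / 100, tolerance = 1e-8)
})

test_that("H2 model carries the printed masses, smoothings and sign structure", {
  m <- build_h2_model(M = 1836)
  expect_equal(m$params$mu_e, 0.99973, tolerance = 1e-4)
  expect_equal(m$params$mu_n, 918)
  # e-e repulsive at contact, e-n attractive at coincidence
  ee <- m$pairs[[1]]$f(matrix(0), matrix(0))
  expect_equal(ee, 1 / sqrt(2), tolerance = 1e-12)
  en <- m$pairs[[2]]$f(matrix(1), matrix(2)) # electron at +R/2 for R = 2
  expect_true(en < 0)
  expect_equal(m$pairs[[2]]$f(matrix(0.5), matrix(1)),
               -1 - 1 / sqrt(2), tolerance = 1e-12)
})

test_that("assembled Hamiltonians are Hermitian and exchange-symmetric", {
  for (m in list(build_h2_model(), build_scattering_model())) {
    axes <- if (identical(m$name, "h2"))
      list(grid_axis(-5, 5, 9), grid_axis(-5, 5, 9), grid_axis(0.5, 4, 8))
    else list(grid_axis(-5, 25, 10), grid_axis(-5, 25, 10))
    g <- system_grid(m, axes)
    H <- hamiltonian_sparse(m, g)
    expect_lt(max(abs(H - Matrix::t(H))), 1e-12)
    # electron-label swap permutation commutes with H
    perm_dims <- if (identical(m$name, "h2")) c(2, 1, 3) else c(2, 1)
    P <- as.vector(aperm(array(seq_len(prod(g$n)), g$n), perm_dims))
    expect_lt(max(abs(H - H[P, P])), 1e-12)
  }
})

test_that("scattering model places the target well at r = 10 with unit depth", {
  m <- build_scattering_model()
  v0 <- m$one_body[[1]]
  expect_equal(v0(matrix(10)), -1)
  expect_lt(abs(v0(matrix(10 + 500))), 3e-3)
  # e-e term symmetric under exchange of arguments
  r <- matrix(c(-3, 7), 2, 1)
  expect_equal(m$pairs[[1]]$f(matrix(r[1]), matrix(r[2])),
               m$pairs[[1]]$f(matrix(r[2]), matrix(r[1])))
})

test_that("Shin-Metiu potential: screened interactions finite, bare fixed-ion terms divergent", {
  m <- build_shin_metiu_model()
  # electron-proton coincidence finite
  expect_true(is.finite(m$pairs[[1]]$f(matrix(1.3), matrix(1.3))))
  # proton one-body diverges approaching the fixed ions at +-L/2
  vR <- m$one_body[[2]]
  expect_gt(vR(matrix(9.49)), vR(matrix(9.0)))
  expect_gt(vR(matrix(9.499)), 100 / 9.5) # blow-up, not a plateau
  w_near <- vR(matrix(c(9.4, 9.49, 9.499)))
  expect_true(all(diff(w_near) > 0))
})

test_that("conical-intersection model is mirror-symmetric and finite", {
  m <- build_ci_model()
  ve <- m$one_body[[1]]; vp <- m$one_body[[2]]
  pts <- cbind(runif(20, -3, 3), runif(20, -2, 3))
  refl <- cbind(-pts[, 1], pts[, 2])
  expect_equal(ve(pts), ve(refl), tolerance = 1e-12)
  expect_equal(vp(pts), vp(refl), tolerance = 1e-12)
  g <- system_grid(m, list(list(grid_axis(-4, 4, 10), grid_axis(-4, 4, 10)),
                           list(grid_axis(-3, 3, 10), grid_axis(-3, 3, 10))))
  W <- potential_array(m, g)
  expect_true(all(is.finite(W)))
  H <- hamiltonian_sparse(m, g)
  expect_lt(max(abs(H - Matrix::t(H))), 1e-12)
})

test_that("clamped-proton electronic surfaces of the CI model are degenerate at the origin", {
  # one electron in three equal wells: the D3h-degenerate pair is the first
  # and second excited states (the ground state is totally symmetric)
  m <- build_ci_model()
  sub <- electronic_submodel(m, 2L)
  ge <- system_grid(sub$model, list(list(grid_axis(-5, 5, 36), grid_axis(-5, 5, 36))))
  bt_ci <- compute_bopes(m, ge, matrix(c(0, 0), 1, 2), 2L, k = 3)
  gap_ci <- bt_ci$surfaces[1, 3] - bt_ci$surfaces[1, 2]
  # displaced geometry for comparison: clearly split
  bt_off <- compute_bopes(m, ge, matrix(c(0.5, 0.9), 1, 2), 2L, k = 3)
  gap_off <- bt_off$surfaces[1, 3] - bt_off$surfaces[1, 2]
  # a square grid only respects the 3-fold symmetry to discretization
  # accuracy, so the degeneracy closes to ~1e-3 rather than machine zero
  expect_lt(gap_ci, 5e-3)
  expect_gt(gap_off, 20 * gap_ci)
})

test_that("pulse field vanishes outside the envelope and peaks mid-pulse", {
  p <- laser_pulse(E0 = 0.006, omega = 0.1, Tpulse = 20)
  expect_equal(field_value(p, 0), 0)
  expect_equal(field_value(p, 25), 0)
  expect_equal(field_value(p, 10), 0.006 * sin(1), tolerance = 1e-12)
  expect_error(field_value(p, -1), "negative")
  p0 <- laser_pulse(E0 = 0, omega = 1, Tpulse = 10)
  expect_true(all(field_value(p0, seq(0, 30, 0.7)) == 0))
  # cycles convention: T = cycles * 2 pi / omega
  p2 <- laser_pulse(E0 = 1, omega = 0.403, cycles = 20)
  expect_equal(p2$Tpulse, 20 * 2 * pi / 0.403)
})
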