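test_that("fixtures are deterministic and carry the advertised content", {
  f1 <- generate_fixture("sampled_ensembles", seed = 4L)
  f2 <- generate_fixture("sampled_ensembles", seed = 4L)
  expect_identical(f1$ensemble$configs, f2$ensemble$configs)
  fa <- generate_fixture("analytic_states")
  # harmonic eigenstates: Rayleigh quotients equal the closed-form energies
  H <- hamiltonian_sparse(fa$model, fa$grid)
  dv <- grid_dvol(fa$grid)
  for (n in 1:3) {
    v <- as.vector(fa$states[[n]]$psi)
    E <- Re(sum(Conj(v) * as.vector(H %*% Re(v))) * dv)
    expect_equal(E, fa$energies[n], tolerance = 1e-4)
  }
  tg <- generate_fixture("tiny_grids")
  expect_named(tg, c("ho", "h2", "scattering"))
  expect_s3_class(tg$h2$grid, "cwf_grid")
})

test_that("guess density is a valid sampling source for every bundled model", {
  models <- list(
    list(m = build_scattering_model(),
         axes = list(grid_axis(-30, 40, 48), grid_axis(-30, 40, 48))),
    list(m = build_shin_metiu_model(),
         axes = list(grid_axis(-20, 20, 48), grid_axis(-8, 8, 32))))
  for (spec in models) {
    g <- system_grid(spec$m, spec$axes)
    d <- guess_density(spec$m, g)
    expect_length(d, g$dims)
    for (a in seq_len(g$dims)) {
      expect_true(all(d[[a]] >= 0))
      expect_gt(sum(d[[a]]), 0)
    }
    ens <- suppressWarnings(sample_configurations(d, g, 8L, seed = 2L))
    expect_equal(dim(ens$configs), c(8L, g$dims))
  }
})

test_that("clamped electronic models reproduce the clamped potential of the full model", {
  m <- build_shin_metiu_model()
  cm <- clamped_model(m, 2L, -2)
  g1 <- system_grid(cm$model, list(grid_axis(-20, 20, 64)))
  v <- cm$model$one_body[[1]](cwfdyn:::block_coords(g1, 1))
  full_g <- system_grid(m, list(grid_axis(-20, 20, 64), grid_axis(-8, 8, 16)))
  ref <- conditional_potential_values(m, full_g, 1L, c(NA, -2))
  expect_equal(v, ref, tolerance = 1e-12)
  expect_equal(cm$const, m$one_body[[2]](matrix(-2)), tolerance = 1e-12)
})

test_that("a tiny end-to-end example run writes its resolved config and series", {
  out <- withr::local_tempdir()
  res <- suppressWarnings(
    run_example("bopes_h2",
                config = list(Nc = 8L, M = 2L, k = 2L, n_r = 24, r_extent = 12,
                              Rvals = c(1.5, 2.0)),
                outdir = out))
  expect_true(file.exists(file.path(out, "resolved_config.yaml")))
  expect_true(file.exists(file.path(out, "surfaces.csv")))
  cfg <- yaml::read_yaml(file.path(out, "resolved_config.yaml"))
  expect_equal(cfg$Nc, 8L)
  expect_true(is.finite(res$max_deviation))
  # re-running from the resolved config reproduces the numbers exactly
  res2 <- suppressWarnings(run_example("bopes_h2", config = cfg))
  expect_identical(res$surfaces, res2$surfaces)
})

test_that("scattering initial state is a normalized spatial-singlet with the stated packets", {
  m <- build_scattering_model()
  g <- system_grid(m, list(grid_axis(-40, 40, 128), grid_axis(-40, 40, 128)))
  wf <- scattering_initial_state(m, g, p = 1.5)
  expect_equal(wf_norm(wf), 1, tolerance = 1e-10)
  expect_lt(max(Mod(wf$psi - t(wf$psi))), 1e-12) # exchange-symmetric
  # momentum expectation shared between the two (symmetrized) electrons;
  # the forward difference measures sin(p dx)/dx rather than p
  dx <- g$axes[[1]]$dx
  k1 <- Im(sum(Conj(wf$psi[-128, ]) * diff(wf$psi)) / dx) * grid_dvol(g)
  expect_equal(k1, sin(1.5 * dx) / dx / 2, tolerance = 0.02)
})
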