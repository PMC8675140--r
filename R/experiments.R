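#' Default guess density for configuration sampling
#'
#' The default guess used throughout the package: the product of per-block
#' densities of the conditional ground states of each block's conditional
#' Hamiltonian, with all other blocks clamped at the classical minimum of
#' the full potential.
#'
#' @param model,grid model and grid; @param n_states number of conditional
#'   states averaged into the guess: 1 for ground-state work; when excited
#'   states are targeted, averaging the lowest `n_states` conditional
#'   densities widens the guess to the regions those states occupy.
#' @return list of per-axis marginal vectors (feed to
#'   [sample_configurations()] in `"marginals"` mode).
#' @export
guess_density <- function(model, grid, n_states = 1L) {
  W <- potential_array(model, grid)
  idx <- arrayInd(which.min(W), grid$n)
  xmin <- vapply(seq_len(grid$dims), function(a) grid$axes[[a]]$x[idx[a]],
                 numeric(1))
  marg <- vector("list", grid$dims)
  for (i in seq_len(nrow(grid$blocks))) {
    Wi <- conditional_potential_values(model, grid, i, xmin)
    ed <- lowest_eigvecs(block_kinetic_matrix(grid, i), Wi, n_states)
    dens <- array(rowMeans(Mod(ed$vectors)^2),
                  dim = grid$n[axes_of_block(grid, i)])
    ax <- axes_of_block(grid, i)
    for (c in seq_along(ax)) {
      marg[[ax[c]]] <- if (length(ax) == 1L) as.vector(dens)
      else as.vector(apply(dens, c, sum))
    }
  }
  marg
}

#' Prepare an ICWF ground state (sampling + basis + imaginary time)
#'
#' @param model,grid model and grid; @param Nc,M ansatz sizes; @param seed
#'   sampling seed; @param density optional sampling density (default: the
#'   [guess_density()] product guess); @param symmetrize symmetrize the
#'   ensemble under identical-particle exchange; @param rcond pseudo-inverse
#'   cutoff; @param k_states states to converge.
#' @return list: `basis`, `solution` (from [imag_time_solve()]), `ensemble`.
#' @export
prepare_icwf_ground <- function(model, grid, Nc, M = 1L, seed = 1L,
                                density = NULL, symmetrize = FALSE,
                                rcond = 1e-8, k_states = 1L,
                                mode = c("marginals", "joint"),
                                kinetic_op = "fd") {
  mode <- match.arg(mode)
  if (is.null(density)) density <- guess_density(model, grid)
  ens <- sample_configurations(density, grid, Nc, seed = seed, mode = mode)
  if (symmetrize) ens <- symmetrize_ensemble(ens)
  basis <- conditional_eigenbasis(model, grid, ens, M = M,
                                  kinetic_op = kinetic_op)
  sol <- imag_time_solve(basis, model, k_states = k_states, rcond = rcond)
  list(basis = basis, solution = sol, ensemble = ens)
}

#' Electronic-only sta-ICWF Born-Oppenheimer surfaces
#'
#' At each clamped nuclear geometry, samples electronic configurations,
#' builds the conditional-eigenstate basis for the electron blocks and
#' solves the projected imaginary-time problem for the `k` lowest surfaces
#' (nuclear-geometry constants included).
#'
#' @param model full model; @param grid_e electronic grid; @param Rvals
#'   nuclear geometries (vector or matrix); @param nuclear_block clamped
#'   block; @param Nc,M ansatz sizes; @param k surfaces; @param seed sampling
#'   seed; @param rcond pseudo-inverse cutoff.
#' @return matrix (`length(Rvals) x k`) of sta-ICWF surfaces.
#' @export
bopes_icwf <- function(model, grid_e, Rvals, nuclear_block, Nc = 32L, M = 5L,
                       k = 5L, seed = 1L, rcond = 1e-10) {
  sub <- electronic_submodel(model, nuclear_block)
  Rmat <- if (is.matrix(Rvals)) Rvals else matrix(Rvals, ncol = 1)
  out <- matrix(NA_real_, nrow(Rmat), k)
  for (r in seq_len(nrow(Rmat))) {
    mR <- clamped_model(model, nuclear_block, Rmat[r, ])
    dens <- guess_density(mR$model, grid_e, n_states = M)
    ens <- sample_configurations(dens, grid_e, Nc, seed = seed + r - 1L)
    basis <- conditional_eigenbasis(mR$model, grid_e, ens, M = M)
    sol <- suppressWarnings(
      imag_time_solve(basis, mR$model, k_states = k, rcond = rcond))
    out[r, ] <- sol$energies + mR$const
  }
  out
}

#' Clamped-nucleus electronic model
#'
#' The electronic sub-model with the nuclear block frozen at geometry `R`:
#' electron-nuclear pair terms become one-body potentials, the
#' nuclear-geometry constant is returned separately.
#'
#' @param model full model; @param nuclear_block block to clamp; @param R
#'   clamped geometry.
#' @return list `model` (electronic `cwf_model`), `const`.
#' @export
clamped_model <- function(model, nuclear_block, R) {
  sub <- electronic_submodel(model, nuclear_block)
  me <- sub$model
  Rrow <- matrix(R, nrow = 1)
  for (p in model$pairs) {
    if (p$i != nuclear_block && p$j != nuclear_block) next
    eblk_old <- if (p$i == nuclear_block) p$j else p$i
    eblk <- sub$remap[eblk_old]
    fpair <- p$f; is_ket <- p$i == nuclear_block
    prev <- me$one_body[[eblk]]
    me$one_body[[eblk]] <- local({
      fp <- fpair; pv <- prev; ket <- is_ket; Rr <- Rrow
      function(X) {
        Rrep <- Rr[rep(1, nrow(X)), , drop = FALSE]
        v <- if (ket) fp(Rrep, X) else fp(X, Rrep)
        if (is.null(pv)) v else v + pv(X)
      }
    })
  }
  list(model = me, const = sub$clamped_const(R))
}

#' Scattering initial wavepacket
#'
#' The spin-singlet spatial state: a symmetrized product of the target-atom
#' ground orbital and an incident Gaussian wavepacket
#' \eqn{\phi_{WP}(r) = (2\alpha/\pi)^{1/4} e^{-\alpha(r-r_0)^2 + ip(r-r_0)}}
#' (width parameter `alpha = 0.1`, start `r0 = -10`, momentum `p`).
#'
#' @param model scattering model; @param grid its 2-electron grid; @param p
#'   incident momentum (a.u.); @param alpha Gaussian width parameter; @param
#'   r0 wavepacket center.
#' @return a [grid_wavefunction()].
#' @export
scattering_initial_state <- function(model, grid, p = 1.5, alpha = 0.1,
                                     r0 = -10) {
  ax <- grid$axes[[1]]
  h <- as.matrix(kinetic_matrix(ax, 1)) + diag(model$one_body[[1]](matrix(ax$x)))
  ed <- eigen(h, symmetric = TRUE)
  phiH <- ed$vectors[, which.min(ed$values)] / sqrt(ax$dx)
  if (phiH[which.max(abs(phiH))] < 0) phiH <- -phiH
  phiWP <- (2 * alpha / pi)^0.25 * exp(-alpha * (ax$x - r0)^2 +
                                         1i * p * (ax$x - r0))
  psi <- outer(phiWP, phiH) + outer(phiH, phiWP)
  grid_wavefunction(grid, psi)
}

#' Run one of the bundled example experiments
#'
#' Config-driven, seeded, desk-scale reproductions of the package's six
#' reference scenarios: `bopes_h2` (surface scan), `kick_h2` (delta-kick
#' absorption), `drive_h2` (strong-field driving), `scattering` (impact
#' ionization), `shin_metiu` (laser-driven proton-coupled electron transfer)
#' and `conical` (wavepacket through a conical intersection). Each run writes
#' CSV series, a resolved-config YAML and a text summary into `outdir` and
#' returns its numerical products invisibly.
#'
#' @param name example name; @param config named list of overrides (see
#'   [example_defaults()]); @param outdir output directory (created); files
#'   are skipped when NULL.
#' @return invisible list of results (series, spectra, deviations).
#' @export
run_example <- function(name = c("bopes_h2", "kick_h2", "drive_h2",
                                 "scattering", "shin_metiu", "conical"),
                        config = list(), outdir = NULL) {
  name <- match.arg(name)
  cfg <- utils::modifyList(example_defaults(name), config)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  res <- switch(name,
                bopes_h2 = example_bopes_h2(cfg),
                kick_h2 = example_kick_h2(cfg),
                drive_h2 = example_drive_h2(cfg),
                scattering = example_scattering(cfg),
                shin_metiu = example_shin_metiu(cfg),
                conical = example_conical(cfg))
  if (!is.null(outdir)) {
    yaml::write_yaml(cfg, file.path(outdir, "resolved_config.yaml"))
    for (nm in names(res)) {
      if (inherits(res[[nm]], "data.frame"))
        write_series_csv(res[[nm]], file.path(outdir, paste0(nm, ".csv")))
    }
    if (!is.null(res$summary))
      writeLines(res$summary, file.path(outdir, "summary.txt"))
  }
  invisible(res)
}

#' Desk-scale default configurations of the bundled examples
#' @param name example name.
#' @export
example_defaults <- function(name) {
  switch(name,
         bopes_h2 = list(seed = 1L, Nc = 32L, M = 5L, k = 5L,
                         r_extent = 16, n_r = 64,
                         Rvals = seq(0.6, 6, length.out = 10)),
         kick_h2 = list(seed = 1L, Nc = 512L, M = 3L, kappa = 0.01,
                        n_r = 48, r_extent = 18, n_R = 32, R_min = 0.3,
                        R_max = 5.2, dt_oracle = 0.15, Tmax = 1000,
                        stride = 4L, mtef_traj = 8L, dt_mtef = 0.2,
                        sampling = "oracle", rcond = 1e-8,
                        run_oracle = TRUE, run_mtef = TRUE),
         drive_h2 = list(seed = 1L, Nc = 512L, M = 3L, E0 = 0.005,
                         omega = 0.403, cycles = 20, n_r = 48, r_extent = 18,
                         n_R = 32, R_min = 0.3, R_max = 5.2, dt = 0.1,
                         Tmax = 450, stride = 10L),
         scattering = list(seed = 1L, Nc = 64L, p = 1.5, alpha = 0.1,
                           n_r = 384, r_min = -60, r_max = 90,
                           dt = 0.05, Tmax = 35.1, stride = 20L,
                           n_independent = 1L, run_oracle = TRUE),
         shin_metiu = list(seed = 1L, Nc = 32L, M = 1L, E0 = 0.006,
                           Tpulse = 827, n_r = 128, r_extent = 25, n_R = 64,
                           R_extent = 9, dt = 0.25, dt_oracle = 0.2,
                           Tmax = 1500, stride = 100L,
                           run_oracle = TRUE, run_mtef = FALSE,
                           mtef_traj = 16L),
         conical = list(seed = 1L, Nc = 16L, n_e = 24, e_extent = 5,
                        n_N = 24, N_min = -2, N_max = 2, Mass = 1836,
                        dt = 0.25, Tmax = 120, stride = 20L, sigma_w = 5,
                        Rc = c(0, 0.3), run_oracle = TRUE),
         stop("unknown example"))
}

example_bopes_h2 <- function(cfg) {
  model <- build_h2_model()
  sub <- electronic_submodel(model, 3L)
  ge <- system_grid(sub$model, list(grid_axis(-cfg$r_extent, cfg$r_extent, cfg$n_r),
                                    grid_axis(-cfg$r_extent, cfg$r_extent, cfg$n_r)))
  exact <- compute_bopes(model, ge, cfg$Rvals, 3L, k = cfg$k)
  icwf <- bopes_icwf(model, ge, cfg$Rvals, 3L, Nc = cfg$Nc, M = cfg$M,
                     k = cfg$k, seed = cfg$seed)
  dev <- abs(icwf - exact$surfaces)
  surf <- data.frame(R = cfg$Rvals)
  for (g in seq_len(cfg$k)) {
    surf[[paste0("exact_", g)]] <- exact$surfaces[, g]
    surf[[paste0("icwf_", g)]] <- icwf[, g]
  }
  list(surfaces = surf, max_deviation = max(dev),
       summary = sprintf("BOPES sta-ICWF (Nc=%d, M=%d): max |deviation| = %.3e hartree over %d R points x %d surfaces",
                         cfg$Nc, cfg$M, max(dev), length(cfg$Rvals), cfg$k))
}

h2_grid <- function(cfg) {
  model <- build_h2_model()
  grid <- system_grid(model, list(
    grid_axis(-cfg$r_extent, cfg$r_extent, cfg$n_r),
    grid_axis(-cfg$r_extent, cfg$r_extent, cfg$n_r),
    grid_axis(cfg$R_min, cfg$R_max, cfg$n_R)))
  list(model = model, grid = grid)
}

example_kick_h2 <- function(cfg) {
  mg <- h2_grid(cfg)
  out <- list()
  gs <- imag_time_states(mg$model, mg$grid, k = 1)
  if (identical(cfg$sampling, "guess")) {
    dens <- NULL; mode <- "marginals"
  } else {
    dens <- Mod(gs$states[[1]]$psi)^2; mode <- "joint"
  }
  prep <- prepare_icwf_ground(mg$model, mg$grid, cfg$Nc, cfg$M,
                              seed = cfg$seed, density = dens, mode = mode,
                              kinetic_op = "fft")
  st <- icwf_state(prep$basis, mg$model, prep$solution$coefficients[[1]],
                   S = prep$solution$S, H = prep$solution$H,
                   rcond = cfg$rcond)
  st <- kick_state(st, cfg$kappa)
  icwf <- sta_propagate(st, dt = cfg$dt_oracle * cfg$stride,
                        Tmax = cfg$Tmax, method = "spectral")
  out$icwf_series <- icwf$series
  out$icwf_spectrum <- absorption_spectrum(icwf$series, cfg$kappa)
  out$E0_icwf <- prep$solution$energies[1]
  if (isTRUE(cfg$run_oracle)) {
    psi0 <- gs$states[[1]]
    D <- dipole_array(mg$model, mg$grid)
    kicked <- grid_wavefunction(mg$grid, psi0$psi * exp(1i * cfg$kappa * D),
                                normalize = FALSE)
    orc <- exact_propagate(mg$model, mg$grid, kicked, dt = cfg$dt_oracle,
                           Tmax = cfg$Tmax, stride = cfg$stride,
                           mask = grid_mask(mg$grid, 0.12))
    out$oracle_series <- orc$series
    out$oracle_spectrum <- absorption_spectrum(orc$series, cfg$kappa)
    out$E0_oracle <- gs$energies[1]
  }
  if (isTRUE(cfg$run_mtef)) {
    sub <- electronic_submodel(mg$model, 3L)
    ge <- system_grid(sub$model,
                      list(mg$grid$axes[[1]], mg$grid$axes[[2]]))
    rd <- reduced_density(gs$states[[1]], 3L)
    xg <- rd$axes[[1]]$x; pg <- rd$density / sum(rd$density)
    nst <- list(mean = sum(xg * pg), var = sum((xg - sum(xg * pg))^2 * pg))
    mt <- ehrenfest_baseline(mg$model, ge, 3L, cfg$mtef_traj,
                             dt = cfg$dt_mtef, Tmax = cfg$Tmax,
                             seed = cfg$seed, nuclear_stats = nst,
                             pulse = laser_pulse(kick = cfg$kappa),
                             stride = max(1L, round(cfg$dt_oracle * cfg$stride / cfg$dt_mtef)))
    out$mtef_series <- mt$series
    out$mtef_spectrum <- absorption_spectrum(mt$series, cfg$kappa)
  }
  if (!is.null(out$oracle_series)) {
    d_ic <- out$icwf_series$mu - out$icwf_series$mu[1]
    d_or <- out$oracle_series$mu - out$oracle_series$mu[1]
    n <- min(length(d_ic), length(d_or))
    out$rel_l2 <- sqrt(sum((d_ic[1:n] - d_or[1:n])^2) / sum(d_or[1:n]^2))
    out$summary <- sprintf("delta-kick dipole: relative L2 (ICWF vs oracle) = %.3f", out$rel_l2)
  }
  out
}

# mean/variance of the ground-state nuclear marginal (for Wigner sampling)
nuclear_marginal_stats <- function(model, grid, nuclear_block = 3L) {
  gs <- imag_time_states(model, grid, k = 1)
  rd <- reduced_density(gs$states[[1]], nuclear_block)
  x <- rd$axes[[1]]$x; p <- rd$density / sum(rd$density)
  m <- sum(x * p)
  list(mean = m, var = sum((x - m)^2 * p))
}

example_drive_h2 <- function(cfg) {
  mg <- h2_grid(cfg)
  pulse <- laser_pulse(E0 = cfg$E0, omega = cfg$omega, cycles = cfg$cycles)
  prep <- prepare_icwf_ground(mg$model, mg$grid, cfg$Nc, cfg$M, seed = cfg$seed)
  st <- icwf_state(prep$basis, mg$model, prep$solution$coefficients[[1]],
                   S = prep$solution$S, H = prep$solution$H)
  icwf <- sta_propagate(st, dt = cfg$dt, Tmax = cfg$Tmax, pulse = pulse,
                        stride = cfg$stride)
  sr <- icwf$series
  sr$mu_e <- sr$x1 + sr$x2
  sr$R <- sr$x3
  list(icwf_series = sr,
       summary = sprintf("driven H2 (E0=%g, omega=%g): <R> range [%.3f, %.3f]",
                         cfg$E0, cfg$omega, min(sr$R), max(sr$R)))
}

example_scattering <- function(cfg) {
  model <- build_scattering_model()
  grid <- system_grid(model, list(grid_axis(cfg$r_min, cfg$r_max, cfg$n_r),
                                  grid_axis(cfg$r_min, cfg$r_max, cfg$n_r)))
  wf0 <- scattering_initial_state(model, grid, p = cfg$p, alpha = cfg$alpha)
  out <- list()
  dens_acc <- NULL
  for (rep in seq_len(cfg$n_independent)) {
    ens <- sample_configurations(wf0, grid, cfg$Nc,
                                 seed = cfg$seed + 1000L * (rep - 1L),
                                 mode = "joint")
    ens <- symmetrize_ensemble(ens)
    basis <- slice_basis(model, grid, wf0, ens, kinetic_op = "fft")
    fit <- icwf_fit_coefficients(basis, wf0)
    st <- dyn_state(basis, model, fit$C)
    run <- dyn_propagate(st, dt = cfg$dt, Tmax = cfg$Tmax, stride = cfg$stride)
    rd <- reduced_density(run$state, 1L, particles = 2)
    dens_acc <- if (is.null(dens_acc)) rd$density else dens_acc + rd$density
    if (rep == 1L) out$icwf_series <- run$series
  }
  r <- grid$axes[[1]]$x
  out$icwf_density <- data.frame(r = r, rho_e = as.vector(dens_acc) / cfg$n_independent)
  if (isTRUE(cfg$run_oracle)) {
    orc <- exact_propagate(model, grid, wf0, dt = cfg$dt, Tmax = cfg$Tmax,
                           stride = cfg$stride, mask = grid_mask(grid, 0.08))
    rdo <- reduced_density(orc$psi, 1L, particles = 2)
    out$oracle_density <- data.frame(r = r, rho_e = as.vector(rdo$density))
    out$rel_l2 <- sqrt(sum((out$icwf_density$rho_e - rdo$density)^2) /
                         sum(rdo$density^2))
    out$oracle_series <- orc$series
    out$summary <- sprintf("scattering p=%g, t=%.2f fs: reduced-density relative L2 (dyn-ICWF vs oracle) = %.3f",
                           cfg$p, cfg$Tmax * 0.024188843, out$rel_l2)
  }
  out
}

example_shin_metiu <- function(cfg) {
  model <- build_shin_metiu_model()
  grid <- system_grid(model, list(grid_axis(-cfg$r_extent, cfg$r_extent, cfg$n_r),
                                  grid_axis(-cfg$R_extent, cfg$R_extent, cfg$n_R)))
  sub <- electronic_submodel(model, 2L)
  ge <- system_grid(sub$model, list(grid$axes[[1]]))
  bt <- compute_bopes(model, ge, grid$axes[[2]]$x, 2L, k = 2,
                      keep_states = TRUE)
  gs <- exact_eigenstates(model, grid, k = 1)
  Req <- expectation(gs$states[[1]],
                     operator_descriptor(one_body = list(NULL, function(X) X[, 1])))
  iR <- which.min(abs(grid$axes[[2]]$x - Req))
  omega <- bt$surfaces[iR, 2] - bt$surfaces[iR, 1]
  pulse <- laser_pulse(E0 = cfg$E0, omega = omega, Tpulse = cfg$Tpulse)
  out <- list(Req = Req, omega = omega)
  # ICWF: ground by imaginary time in a sampled basis, then dyn propagation
  prep <- prepare_icwf_ground(model, grid, cfg$Nc, cfg$M, seed = cfg$seed,
                              density = Mod(gs$states[[1]]$psi)^2,
                              mode = "joint", kinetic_op = "fft")
  st <- dyn_state(prep$basis, model, prep$solution$coefficients[[1]])
  snap_t <- seq(0, cfg$Tmax, by = cfg$dt * cfg$stride)[-1]
  run <- dyn_propagate(st, dt = cfg$dt, Tmax = cfg$Tmax, pulse = pulse,
                       stride = cfg$stride, snapshot_times = snap_t)
  pop <- populations_from_snapshots(run$snapshots, bt, model, grid)
  out$icwf_series <- cbind(run$series[seq_len(nrow(pop)) , ], pop[, -1])
  if (isTRUE(cfg$run_oracle)) {
    orc <- exact_propagate(model, grid, gs$states[[1]], dt = cfg$dt_oracle,
                           Tmax = cfg$Tmax, pulse = pulse,
                           stride = round(cfg$dt * cfg$stride / cfg$dt_oracle),
                           snapshot_times = snap_t)
    popo <- rbind(
      data.frame(time_au = 0,
                 P1 = adiabatic_populations(gs$states[[1]], bt, model, 2)$P[1],
                 P2 = adiabatic_populations(gs$states[[1]], bt, model, 2)$P[2],
                 D12 = decoherence_indicator(gs$states[[1]], bt, model)),
      do.call(rbind, lapply(orc$snapshots, function(sn) {
        ap <- adiabatic_populations(sn, bt, model, 2)
        data.frame(time_au = sn$time, P1 = ap$P[1], P2 = ap$P[2],
                   D12 = decoherence_indicator(sn, bt, model))
      })))
    out$oracle_series <- cbind(orc$series[seq_len(nrow(popo)), ], popo[, -1])
  }
  if (isTRUE(cfg$run_mtef)) {
    nst <- list(mean = Req,
                var = {
          rd <- reduced_density(gs$states[[1]], 2L)
          x <- rd$axes[[1]]$x; p <- rd$density / sum(rd$density)
          sum((x - sum(x * p))^2 * p)
        })
    mt <- ehrenfest_baseline(model, ge, 2L, cfg$mtef_traj, dt = 0.5,
                             Tmax = cfg$Tmax, seed = cfg$seed,
                             nuclear_stats = nst, pulse = pulse,
                             stride = round(cfg$dt * cfg$stride / 0.5),
                             bopes = bt)
    out$mtef_series <- mt$series
  }
  out$summary <- sprintf("Shin-Metiu drive: <R>_0 = %.3f, omega = %.4f au", Req, omega)
  out
}

# per-axis marginals of a grid state, for sampling
sample_density_marginals <- function(wf, grid) {
  dens <- Mod(wf$psi)^2
  lapply(seq_len(grid$dims), function(a) as.vector(apply(dens, a, sum)))
}

# project dyn-ICWF snapshots (2-block models) on a BOPES table
populations_from_snapshots <- function(snaps, bopes, model, grid) {
  rows <- lapply(snaps, function(sn) {
    wf <- reconstruct_wavefunction(sn$basis, sn$C, normalize = TRUE)
    ap <- adiabatic_populations(wf, bopes, model, 2)
    data.frame(time_au = sn$t, P1 = ap$P[1], P2 = ap$P[2],
               D12 = decoherence_indicator(wf, bopes, model))
  })
  first <- data.frame(time_au = 0, P1 = NA, P2 = NA, D12 = NA)
  out <- rbind(first, do.call(rbind, rows))
  out
}

example_conical <- function(cfg) {
  model <- build_ci_model(M = cfg$Mass)
  axes_e <- list(grid_axis(-cfg$e_extent, cfg$e_extent, cfg$n_e),
                 grid_axis(-cfg$e_extent, cfg$e_extent, cfg$n_e))
  axes_N <- list(grid_axis(cfg$N_min, cfg$N_max, cfg$n_N),
                 grid_axis(cfg$N_min, cfg$N_max, cfg$n_N))
  grid <- system_grid(model, list(axes_e, axes_N))
  wf0 <- ci_initial_state(model, grid, Rc = cfg$Rc, sigma_w = cfg$sigma_w)
  out <- list()
  ens <- sample_configurations(wf0, grid, cfg$Nc, seed = cfg$seed, mode = "joint")
  basis <- slice_basis(model, grid, wf0, ens, kinetic_op = "fft")
  fit <- icwf_fit_coefficients(basis, wf0)
  st <- dyn_state(basis, model, fit$C)
  run <- dyn_propagate(st, dt = cfg$dt, Tmax = cfg$Tmax, stride = cfg$stride)
  out$icwf_series <- run$series
  rd <- reduced_density(run$state, 2L)
  out$icwf_nuclear_density <- rd$density
  if (isTRUE(cfg$run_oracle)) {
    orc <- exact_propagate(model, grid, wf0, dt = cfg$dt, Tmax = cfg$Tmax,
                           stride = cfg$stride)
    rdo <- reduced_density(orc$psi, 2L)
    out$oracle_nuclear_density <- rdo$density
    out$oracle_series <- orc$series
    out$rel_l2 <- sqrt(sum((rd$density - rdo$density)^2) / sum(rdo$density^2))
    out$summary <- sprintf("conical intersection, t=%.1f au: nuclear-density relative L2 (dyn-ICWF vs oracle) = %.3f",
                           cfg$Tmax, out$rel_l2)
  }
  out
}

#' Deterministic miniature fixtures for tests and demos
#'
#' @param kind `"tiny_grids"` (small model + grid pairs), `"analytic_states"`
#'   (harmonic eigenstates with closed-form energies) or
#'   `"sampled_ensembles"` (frozen seeded configuration ensembles).
#' @param seed seed for the sampled ensembles.
#' @return a named list of fixture objects.
#' @export
generate_fixture <- function(kind = c("tiny_grids", "analytic_states",
                                      "sampled_ensembles"), seed = 1L) {
  kind <- match.arg(kind)
  ho <- model_system(data.frame(label = "x", dim = 1L, mass = 1, charge = 0),
                     one_body = list(function(X) 0.5 * X[, 1]^2),
                     dipole = list(1), name = "ho")
  if (kind == "tiny_grids") {
    h2 <- build_h2_model()
    sc <- build_scattering_model()
    return(list(
      ho = list(model = ho, grid = system_grid(ho, list(grid_axis(-8, 8, 32)))),
      h2 = list(model = h2,
                grid = system_grid(h2, list(grid_axis(-10, 10, 24),
                                            grid_axis(-10, 10, 24),
                                            grid_axis(0.4, 4, 16)))),
      scattering = list(model = sc,
                        grid = system_grid(sc, list(grid_axis(-30, 40, 32),
                                                    grid_axis(-30, 40, 32))))))
  }
  if (kind == "analytic_states") {
    g <- system_grid(ho, list(grid_axis(-9, 9, 192)))
    x <- g$axes[[1]]$x
    herm <- list(rep(1, 192), 2 * x, 4 * x^2 - 2)
    states <- lapply(0:2, function(n)
      grid_wavefunction(g, herm[[n + 1]] * exp(-x^2 / 2)))
    return(list(model = ho, grid = g, states = states,
                energies = c(0.5, 1.5, 2.5)))
  }
  sc <- build_scattering_model()
  g <- system_grid(sc, list(grid_axis(-30, 40, 64), grid_axis(-30, 40, 64)))
  wf <- scattering_initial_state(sc, g, p = 1.0)
  list(model = sc, grid = g,
       ensemble = sample_configurations(wf, g, 16L, seed = seed, mode = "joint"))
}

#' Initial state for the conical-intersection example
#'
#' Direct product of the first excited clamped-proton electronic state
#' (phase-aligned over the nuclear grid outward from the packet center) and
#' a nuclear Gaussian \eqn{\chi(R) \propto e^{-\sigma_w |R - R_c|^2}}.
#'
#' @param model CI model; @param grid its 4D grid; @param Rc packet center;
#' @param sigma_w Gaussian exponent (a.u.).
#' @export
ci_initial_state <- function(model, grid, Rc = c(0, 0.4), sigma_w = 5) {
  axN <- axes_of_block(grid, 2L)
  RN <- block_coords(grid, 2L)
  chi <- exp(-sigma_w * ((RN[, 1] - Rc[1])^2 + (RN[, 2] - Rc[2])^2))
  sub <- electronic_submodel(model, 2L)
  ge <- system_grid(sub$model, list(list(grid$axes[[1]], grid$axes[[2]])))
  bt <- compute_bopes(model, ge, RN, 2L, k = 2, keep_states = TRUE,
                      align_from = Rc)
  nE <- prod(ge$n)
  psi <- matrix(0 + 0i, nE, nrow(RN))
  for (r in seq_len(nrow(RN))) psi[, r] <- bt$states[[r]][, 2] * chi[r]
  grid_wavefunction(grid, array(psi, dim = grid$n))
}
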