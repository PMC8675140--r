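#' Multi-trajectory Ehrenfest (MTEF) mean-field baseline
#'
#' Classical nuclear trajectories sampled from a Gaussian Wigner
#' approximation of the initial nuclear state, each coupled to an exact
#' quantum electronic wavefunction on the electronic grid through mean-field
#' forces. Used as the mean-field comparison that the ICWF methods are meant
#' to beat: it misses electron-nuclear correlation (vibronic peak spacing)
#' and decoherence.
#'
#' @param model a `cwf_model` with one 1D nuclear block; @param grid_e
#'   electronic grid (a `cwf_grid` of [electronic_submodel()]); @param
#'   nuclear_block index of the classical block; @param n_traj number of
#'   trajectories; @param dt time step; @param Tmax propagation length;
#' @param seed sampling seed; @param nuclear_stats list with `mean` and `var`
#'   of the initial nuclear position (momentum variance is the minimal
#'   -uncertainty partner `1/(4 var)`); @param pulse optional [laser_pulse()]
#'   -- its `kick` is applied impulsively at t = 0 and its field drives the
#'   electronic dipole; @param stride record every `stride` steps; @param
#'   bopes optional `bopes_table` with electronic states tabulated at nuclear
#'   grid points: adds per-surface populations `P1..Pk` and the decoherence
#'   channel `D12`.
#' @return list `series` (trajectory-averaged observables), `traj_R` (matrix
#'   of nuclear paths).
#' @export
ehrenfest_baseline <- function(model, grid_e, nuclear_block, n_traj, dt, Tmax,
                               seed = 1L, nuclear_stats, pulse = NULL,
                               stride = 1L, bopes = NULL) {
  sub <- electronic_submodel(model, nuclear_block)
  mass_n <- model$blocks$mass[nuclear_block]
  d_nuc <- model$dipole[[nuclear_block]][1]
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sdR <- sqrt(nuclear_stats$var)
  R0 <- stats::rnorm(n_traj, nuclear_stats$mean, sdR)
  P0 <- stats::rnorm(n_traj, 0, 1 / (2 * sdR))
  dims_e <- grid_e$n
  dvE <- grid_dvol(grid_e)
  K2e <- kinetic_k2_array(grid_e)
  Kphase <- exp(-1i * dt * K2e)
  De <- dipole_array(sub$model, grid_e)
  V0e <- potential_array(sub$model, grid_e)
  nsteps <- ceiling(Tmax / dt - 1e-12)
  nrec <- length(seq(0, nsteps, by = stride))
  has_field <- !is.null(pulse) && pulse$E0 != 0
  kappa <- if (!is.null(pulse)) pulse$kick else 0
  nP <- if (is.null(bopes)) 0L else bopes$k
  acc_mu <- matrix(0, nrec, 1); acc_R <- matrix(0, nrec, 1)
  acc_P <- if (nP) matrix(0, nrec, nP) else NULL
  traj_R <- matrix(0, nrec, n_traj)
  chan_t <- numeric(nrec)
  # per-surface nuclear weights for the decoherence channel
  wgt_n <- if (nP) array(0, dim = c(nrec, n_traj, nP)) else NULL
  hstep <- 1e-4
  for (tr in seq_len(n_traj)) {
    R <- R0[tr]; P <- P0[tr]
    cl <- sub$clamped_potential(grid_e, R)
    He <- hamiltonian_sparse(sub$model, grid_e) + Matrix::Diagonal(x = cl$diag)
    ed <- lanczos_shift_invert(He, k = 1, sigma = min(V0e + cl$diag) - 0.1,
                               tol = 1e-8)
    psi <- array(ed$vectors[, 1] / sqrt(dvE), dim = dims_e)
    if (kappa != 0) psi <- psi * exp(1i * kappa * De)
    force <- function(psi, R, t) {
      dV <- (sub$clamped_potential(grid_e, R + hstep)$diag -
               sub$clamped_potential(grid_e, R - hstep)$diag) / (2 * hstep)
      dC <- (num_const(sub, R + hstep) - num_const(sub, R - hstep)) / (2 * hstep)
      f <- -sum(dV * Mod(as.vector(psi))^2) * dvE / (sum(Mod(psi)^2) * dvE) - dC
      if (has_field) f <- f + field_value(pulse, t) * d_nuc
      f
    }
    Ft <- force(psi, R, 0)
    ri <- 1L
    record <- function(ri, t, psi, R) {
      dens <- Mod(psi)^2; n2 <- sum(dens) * dvE
      acc_mu[ri, 1] <<- acc_mu[ri, 1] + sum(De * dens) * dvE / n2
      acc_R[ri, 1] <<- acc_R[ri, 1] + R
      traj_R[ri, tr] <<- R
      chan_t[ri] <<- t
      if (nP) {
        rid <- which.min(abs(bopes$Rvals[, 1] - R))
        c_n <- crossprod(Conj(bopes$states[[rid]]), as.vector(psi)) * dvE
        w <- Mod(c_n)^2 / n2
        acc_P[ri, ] <<- acc_P[ri, ] + w
        wgt_n[ri, tr, ] <<- w
      }
    }
    record(ri, 0, psi, R)
    for (s in seq_len(nsteps)) {
      t <- (s - 1) * dt
      Rnew <- R + dt * P / mass_n + dt^2 * Ft / (2 * mass_n)
      Rmid <- (R + Rnew) / 2
      clm <- sub$clamped_potential(grid_e, Rmid)
      Vt <- V0e + array(clm$diag, dims_e)
      ph <- if (has_field) {
        Em <- field_value(pulse, t + dt / 2)
        exp(-1i * dt / 2 * (Vt - Em * De))
      } else exp(-1i * dt / 2 * Vt)
      psi <- ph * psi
      psi <- fft(Kphase * fft(psi), inverse = TRUE) / length(psi)
      psi <- ph * psi
      Fn <- force(psi, Rnew, t + dt)
      P <- P + dt * (Ft + Fn) / 2
      R <- Rnew; Ft <- Fn
      if (s %% stride == 0L) {
        ri <- ri + 1L
        record(ri, s * dt, psi, R)
      }
    }
  }
  series <- data.frame(time_au = chan_t, time_fs = chan_t * 0.024188843,
                       mu = acc_mu[, 1] / n_traj, R = acc_R[, 1] / n_traj)
  if (nP) {
    for (n in seq_len(nP)) series[[paste0("P", n)]] <- acc_P[, n] / n_traj
    # decoherence from the trajectory-binned per-surface nuclear densities
    ax <- NULL
    series$D12 <- vapply(seq_len(nrec), function(ri) {
      mtef_decoherence(traj_R[ri, ], wgt_n[ri, , 1], wgt_n[ri, , 2],
                       bopes$Rvals[, 1])
    }, numeric(1))
  }
  class(series) <- c("observable_series", class(series))
  list(series = series, traj_R = traj_R)
}

num_const <- function(sub, R) sub$clamped_const(R)

# overlap of per-surface nuclear densities estimated from binned trajectories
mtef_decoherence <- function(Rtraj, w1, w2, Rgrid) {
  br <- range(Rgrid)
  nb <- max(8L, min(length(Rgrid) %/% 4L, 64L))
  edges <- seq(br[1], br[2], length.out = nb + 1L)
  dR <- edges[2] - edges[1]
  idx <- pmin(pmax(findInterval(Rtraj, edges), 1L), nb)
  n <- length(Rtraj)
  rho1 <- rho2 <- numeric(nb)
  for (q in seq_len(n)) {
    rho1[idx[q]] <- rho1[idx[q]] + w1[q]
    rho2[idx[q]] <- rho2[idx[q]] + w2[q]
  }
  rho1 <- rho1 / (n * dR); rho2 <- rho2 / (n * dR)
  sum(rho1 * rho2) * dR
}
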