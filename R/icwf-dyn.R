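#' CWF basis from conditional slices of a full wavefunction
#'
#' Builds an `M = 1` basis whose CWFs are the normalized one-body slices of a
#' given full wavefunction at the ensemble's conditioning points (the
#' initialization used when the initial state is known analytically rather
#' than prepared by the imaginary-time eigensolver, e.g. a scattering
#' wavepacket).
#'
#' @param model,grid model and grid; @param wf a [grid_wavefunction()];
#' @param ensemble a [sample_configurations()] result; @param order FD
#'   stencil order; @param pair_rtol pair-kernel SVD truncation.
#' @return a `cwf_basis`.
#' @export
slice_basis <- function(model, grid, wf, ensemble, order = 4L,
                        pair_rtol = 1e-12, kinetic_op = c("fd", "fft")) {
  kinetic_op <- match.arg(kinetic_op)
  X <- if (inherits(ensemble, "configuration_ensemble")) ensemble$configs
  else as.matrix(ensemble)
  Nc <- nrow(X)
  nb <- nrow(grid$blocks)
  psis <- vector("list", nb)
  for (i in seq_len(nb)) {
    P <- matrix(0 + 0i, block_npts(grid, i), Nc)
    for (a in seq_len(Nc)) {
      sl <- conditional_slice(wf, i, X[a, ])
      if (sl$degenerate)
        stop("conditioning point ", a, " lies outside the support of the state")
      P[, a] <- as.vector(sl$normalized)
    }
    psis[[i]] <- P
  }
  K <- lapply(seq_len(nb), function(i) block_kinetic_matrix(grid, i, order))
  kern <- pair_kernel_mats(model, grid)
  structure(list(psis = psis,
                 prov = data.frame(lambda = seq_len(Nc), nu = 1L),
                 traj = X, K = K,
                 pair_svd = pair_kernel_svds(model, grid, pair_rtol, kern),
                 pair_kernel = kern, kinetic_op = kinetic_op,
                 Nc = Nc, M = 1L, grid = grid),
            class = "cwf_basis")
}

#' Fit ICWF coefficients to a target wavefunction
#'
#' Least-squares (pseudo-inverse) projection of a grid wavefunction onto the
#' ansatz span: \eqn{C = S^+ b} with
#' \eqn{b_\alpha = \langle\prod_i\psi_i^\alpha|\Psi\rangle}.
#'
#' @param basis a `cwf_basis`; @param wf target [grid_wavefunction()] on the
#'   basis grid; @param rcond pseudo-inverse cutoff.
#' @return list `C`, `fidelity` (squared overlap of the reconstruction with
#'   the target), `rank`.
#' @export
icwf_fit_coefficients <- function(basis, wf, rcond = 1e-8) {
  grid <- basis$grid
  Ncm <- ncol(basis$psis[[1]])
  nb <- length(basis$psis)
  dv <- grid_dvol(grid)
  b <- complex(Ncm)
  for (a in seq_len(Ncm)) {
    arr <- wf$psi
    for (i in seq_len(nb)) {
      # contract the (always leading, after previous contractions) block axes
      nblk <- block_npts(grid, i)
      arr <- matrix(arr, nrow = nblk)
      arr <- crossprod(Conj(basis$psis[[i]][, a]), arr)
    }
    b[a] <- as.complex(arr) * dv
  }
  S <- overlap_matrix(basis)
  fac <- pinv_factor(S, rcond)
  C <- as.vector(pinv_apply(fac, b))
  n2psi <- sum(Mod(wf$psi)^2) * dv
  n2rec <- Re(sum(Conj(C) * (S %*% C)))
  fid <- Mod(sum(Conj(C) * b))^2 / (n2psi * n2rec)
  list(C = C, fidelity = fid, rank = fac$rank)
}

#' Reconstruct the full wavefunction of an ICWF state
#'
#' \eqn{\Psi = \sum_\alpha C_\alpha \prod_i \psi_i^\alpha} assembled on the
#' full tensor grid (small grids / few blocks only).
#'
#' @param basis a `cwf_basis`; @param C coefficients; @param normalize
#'   renormalize the result.
#' @export
reconstruct_wavefunction <- function(basis, C, normalize = FALSE) {
  grid <- basis$grid
  nb <- length(basis$psis)
  if (nb == 2L) {
    psi <- basis$psis[[1]] %*% (C * t(basis$psis[[2]]))
  } else {
    N <- prod(as.numeric(grid$n))
    if (N * length(C) > 5e7) stop("grid too large for full reconstruction")
    psi <- 0
    for (a in seq_along(C)) {
      v <- basis$psis[[1]][, a]
      for (i in 2:nb) v <- as.vector(outer(v, basis$psis[[i]][, a]))
      psi <- psi + C[a] * v
    }
  }
  grid_wavefunction(grid, array(psi, dim = grid$n), normalize = normalize)
}

# cubic interpolation of every basis column of one block at query points;
# returns value matrix (nq x Ncm) and one derivative matrix per component
interp_block <- function(grid, block, P, pts) {
  ax <- axes_of_block(grid, block)
  if (length(ax) == 1L) {
    r <- interp_cubic(grid$axes[[ax]], P, pts[, 1])
    return(list(value = r$value, deriv = list(r$deriv)))
  }
  a1 <- grid$axes[[ax[1]]]; a2 <- grid$axes[[ax[2]]]
  n1 <- a1$n; n2 <- a2$n; nq <- nrow(pts)
  w1 <- cubic_weights(a1, pts[, 1]); w2 <- cubic_weights(a2, pts[, 2])
  # 16-point tensor stencil as a sparse matrix acting on vec(psi)
  rows <- rep(seq_len(nq), each = 16L)
  i1 <- w1$i0[rows] + rep(rep(0:3, times = 4L), nq)
  i2 <- w2$i0[rows] + rep(rep(0:3, each = 4L), nq)
  colsidx <- i1 + (i2 - 1L) * n1
  wv <- w1$w[cbind(rows, rep(rep(1:4, times = 4L), nq))] *
    w2$w[cbind(rows, rep(rep(1:4, each = 4L), nq))]
  wd1 <- w1$d[cbind(rows, rep(rep(1:4, times = 4L), nq))] *
    w2$w[cbind(rows, rep(rep(1:4, each = 4L), nq))]
  wd2 <- w1$w[cbind(rows, rep(rep(1:4, times = 4L), nq))] *
    w2$d[cbind(rows, rep(rep(1:4, each = 4L), nq))]
  Wv <- Matrix::sparseMatrix(i = rows, j = colsidx, x = wv, dims = c(nq, n1 * n2))
  Wd1 <- Matrix::sparseMatrix(i = rows, j = colsidx, x = wd1, dims = c(nq, n1 * n2))
  Wd2 <- Matrix::sparseMatrix(i = rows, j = colsidx, x = wd2, dims = c(nq, n1 * n2))
  list(value = sp_cmult(Wv, P),
       deriv = list(sp_cmult(Wd1, P), sp_cmult(Wd2, P)))
}

# 4-point Lagrange weights (value + derivative) per query point on one axis
cubic_weights <- function(axis, xq) {
  n <- axis$n
  tt <- (xq - axis$min) / axis$dx
  i0 <- pmin(pmax(floor(tt), 1L), n - 3L)
  s <- tt - i0
  w <- cbind(-s * (s - 1) * (s - 2) / 6,
             (s + 1) * (s - 1) * (s - 2) / 2,
             -(s + 1) * s * (s - 2) / 2,
             (s + 1) * s * (s - 1) / 6)
  d <- cbind((-3 * s^2 + 6 * s - 2) / 6,
             (3 * s^2 - 4 * s - 1) / 2,
             (-3 * s^2 + 2 * s + 2) / 2,
             (3 * s^2 - 1) / 6) / axis$dx
  list(i0 = as.integer(i0), w = w, d = d)
}

#' Bohmian (conditional) velocities of the ICWF trajectories
#'
#' \eqn{v_i^\alpha = \mathrm{Im}[\nabla_i\Psi/\Psi]/m_i} evaluated at each
#' trajectory position, with \eqn{\Psi} and \eqn{\nabla_i\Psi} assembled from
#' the ansatz by off-grid cubic interpolation. Velocities are clamped to zero
#' where the reconstructed density falls below `floor` times its ensemble
#' maximum (the quotient is singular in the tails).
#'
#' @param basis a `cwf_basis` (time-evolved CWFs); @param C coefficients;
#' @param traj trajectory matrix (`N_cM x dims`), defaults to `basis$traj`;
#' @param floor relative density floor.
#' @return velocity matrix (`N_cM x dims`).
#' @export
bohmian_velocities <- function(basis, C, traj = basis$traj, floor = 1e-12) {
  grid <- basis$grid
  nb <- length(basis$psis)
  vals <- vector("list", nb); grads <- vector("list", nb)
  for (i in seq_len(nb)) {
    r <- interp_block(grid, i, basis$psis[[i]], traj[, axes_of_block(grid, i),
                                                     drop = FALSE])
    vals[[i]] <- r$value; grads[[i]] <- r$deriv
  }
  prod_all <- Reduce(`*`, vals)
  D <- as.vector(prod_all %*% C)
  dens <- Mod(D)^2
  ok <- dens >= floor * max(dens)
  V <- matrix(0, nrow(traj), ncol(traj))
  for (i in seq_len(nb)) {
    rest <- if (nb > 1) Reduce(`*`, vals[setdiff(seq_len(nb), i)])
    else matrix(1 + 0i, nrow(traj), length(C))
    m <- grid$blocks$mass[i]
    ax <- axes_of_block(grid, i)
    for (c in seq_along(ax)) {
      Nc_ <- as.vector((grads[[i]][[c]] * rest) %*% C)
      v <- rep(0, nrow(traj))
      v[ok] <- Im(Nc_[ok] / D[ok]) / m
      V[, ax[c]] <- v
    }
  }
  V
}

#' Initialize a dyn-ICWF state
#'
#' @param basis a `cwf_basis` (e.g. from [conditional_eigenbasis()] +
#'   [imag_time_solve()], or [slice_basis()]); @param model the model; @param
#'   C initial coefficients; @param t0 initial time; @param rcond
#'   pseudo-inverse cutoff; @param floor Bohmian density floor; @param
#'   boundary `"reflect"` or `"clamp"` behaviour for trajectories reaching
#'   the grid edge.
#' @return object of class `icwf_state` (mode `"dyn"`).
#' @export
dyn_state <- function(basis, model, C, t0 = 0, rcond = 1e-8, floor = 1e-12,
                      boundary = c("reflect", "clamp")) {
  boundary <- match.arg(boundary)
  structure(list(basis = basis, model = model, C = as.vector(C), t = t0,
                 traj = basis$traj, rcond = rcond, floor = floor,
                 boundary = boundary, mode = "dyn", cache = NULL),
            class = "icwf_state")
}

# one split-operator step of length dtp for every CWF under its conditional
# Hamiltonian (frozen trajectories); exactly norm-preserving per column.
# Each CWF is kept in its energy gauge: the instantaneous conditional energy
# <psi|h|psi> is rotated out of the CWF (and compensated in the coefficient
# equation through dyn_matrices), which removes the fast absolute-energy
# phases from S, H and G and makes the Strang-split coefficient update
# norm-conserving at practical time steps.
propagate_cwfs <- function(basis, model, traj, dtp, t, pulse = NULL) {
  grid <- basis$grid
  for (i in seq_along(basis$psis)) {
    W <- cond_pot_matrix(model, grid, i, traj, t, pulse)
    P0 <- basis$psis[[i]]
    eng <- Re(colSums(Conj(P0) * (apply_block_kinetic(basis, i, P0) + W * P0))) *
      block_dvol(grid, i)
    ph <- exp(-1i * dtp / 2 * W)
    P <- ph * P0
    P <- block_kinetic_fft(P, grid, i, dtp)
    P <- ph * P
    basis$psis[[i]] <- sweep(P, 2, exp(1i * dtp * eng), `*`)
  }
  basis
}

# FFT kinetic propagation of all columns of one block
block_kinetic_fft <- function(P, grid, i, dtp) {
  ax <- axes_of_block(grid, i)
  m <- grid$blocks$mass[i]
  kph <- lapply(grid$axes[ax], function(a) {
    kf <- 2 * pi / (a$n * a$dx) *
      c(0:floor(a$n / 2), -(ceiling(a$n / 2) - 1):-1)[1:a$n]
    exp(-1i * dtp * kf^2 / (2 * m))
  })
  if (length(ax) == 1L) {
    F <- stats::mvfft(P)
    return(stats::mvfft(kph[[1]] * F, inverse = TRUE) / nrow(P))
  }
  n1 <- grid$n[ax[1]]; n2 <- grid$n[ax[2]]
  out <- P
  for (c in seq_len(ncol(P))) {
    A <- matrix(P[, c], n1, n2)
    A <- fft(fft(A) * outer(kph[[1]], kph[[2]]), inverse = TRUE) / (n1 * n2)
    out[, c] <- as.vector(A)
  }
  out
}

# reflect/clamp trajectories into the grid interior
enforce_bounds <- function(traj, grid, boundary) {
  for (a in seq_len(grid$dims)) {
    ax <- grid$axes[[a]]
    lo <- ax$min + 1e-9; hi <- ax$max - 1e-9
    x <- traj[, a]
    if (boundary == "reflect") {
      bad <- x < lo | x > hi
      if (any(bad)) {
        x[x < lo] <- 2 * lo - x[x < lo]
        x[x > hi] <- 2 * hi - x[x > hi]
        x <- pmin(pmax(x, lo), hi)
      }
    } else x <- pmin(pmax(x, lo), hi)
    traj[, a] <- x
  }
  traj
}

# S, G, the one-body part of H and the pseudo-inverse at the current
# basis/trajectories; the pair part of H enters as a matvec (two-block
# models) so the full H matrix is never assembled in the propagation loop
dyn_matrices <- function(basis, model, traj, t, pulse, rcond) {
  Olist <- block_overlaps(basis)
  S <- prod_except(Olist, integer(0))
  S <- (S + Conj(t(S))) / 2
  grid <- basis$grid
  field <- if (is.null(pulse)) 0 else field_value(pulse, t)
  ob <- lapply(seq_along(basis$psis), function(i) {
    Xi <- block_coords(grid, i)
    v <- if (is.null(model$one_body[[i]])) rep(0, nrow(Xi)) else model$one_body[[i]](Xi)
    if (field != 0) v <- v - field * as.vector(Xi %*% model$dipole[[i]])
    v
  })
  H1 <- operator_matrix(basis, one_body = ob, kinetic = TRUE, Olist = Olist)
  G <- coupling_matrix(basis, model, traj, t, pulse, Olist = Olist)
  # energy gauge: the CWFs rotate with e^{+i e_beta t} (propagate_cwfs), so
  # the generator acting on the ket is h - e_beta: G -> G - S * e_beta
  Gt <- G - sweep(S, 2, attr(G, "ket_energy"), `*`)
  two_block <- length(basis$psis) == 2L
  HmGC <- if (two_block) {
    A <- H1 - Gt
    function(C) A %*% C + pair_hamiltonian_matvec(basis, C)
  } else {
    H <- H1 + operator_matrix(basis, pair_svds = basis$pair_svd, Olist = Olist)
    A <- H - Gt
    function(C) A %*% C
  }
  list(S = S, HmGC = HmGC, fac = pinv_factor(S, rcond))
}

#' One dyn-ICWF time step
#'
#' Strang-split update: (a) half-step propagation of every CWF under its
#' conditional Hamiltonian; (b) Heun update of the Bohmian trajectories and
#' refresh of the conditional potentials; (c) second CWF half-step; (d) RK4
#' update of the coefficients under
#' \eqn{i\,dC/dt = S^+(H - G)\,C} with matrices rebuilt at the substep times.
#'
#' @param state an `icwf_state` of mode `"dyn"`; @param dt time step; @param
#'   pulse optional [laser_pulse()].
#' @export
dyn_time_step <- function(state, dt, pulse = NULL) {
  stopifnot(state$mode == "dyn")
  basis <- state$basis; model <- state$model
  t <- state$t; traj <- state$traj
  if (is.null(state$cache))
    state$cache <- dyn_matrices(basis, model, traj, t, pulse, state$rcond)
  Mt <- state$cache
  # (a) CWF half step
  basis <- propagate_cwfs(basis, model, traj, dt / 2, t + dt / 4, pulse)
  # (b) trajectories: Heun with velocities from the midpoint CWFs
  v1 <- bohmian_velocities(basis, state$C, traj, state$floor)
  xs <- enforce_bounds(traj + dt * v1, basis$grid, state$boundary)
  v2 <- bohmian_velocities(basis, state$C, xs, state$floor)
  traj <- enforce_bounds(traj + dt / 2 * (v1 + v2), basis$grid, state$boundary)
  basis$traj <- traj
  # midpoint matrices (CWFs at t + dt/2, refreshed trajectories)
  Mh <- dyn_matrices(basis, model, traj, t + dt / 2, pulse, state$rcond)
  # (c) second CWF half step with refreshed conditional potentials
  basis <- propagate_cwfs(basis, model, traj, dt / 2, t + 3 * dt / 4, pulse)
  Mf <- dyn_matrices(basis, model, traj, t + dt, pulse, state$rcond)
  # (d) RK4 on the coefficients
  f <- function(M, C) -1i * as.vector(pinv_apply(M$fac, M$HmGC(C)))
  C <- state$C
  k1 <- f(Mt, C)
  k2 <- f(Mh, C + dt / 2 * k1)
  k3 <- f(Mh, C + dt / 2 * k2)
  k4 <- f(Mf, C + dt * k3)
  state$C <- C + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  state$basis <- basis; state$traj <- traj; state$t <- t + dt
  state$cache <- Mf
  state
}

#' Propagate a dyn-ICWF state
#'
#' @param state an `icwf_state` (mode `"dyn"`); @param dt step; @param Tmax
#'   propagation length; @param pulse optional pulse; @param stride record
#'   every `stride` steps; @param snapshot_times times at which copies of the
#'   state are stored (for densities).
#' @return list `series` (time, norm, dipole, positions), `state`,
#'   `snapshots`.
#' @export
dyn_propagate <- function(state, dt, Tmax, pulse = NULL, stride = 1L,
                          snapshot_times = numeric(0)) {
  nsteps <- ceiling(Tmax / dt - 1e-12)
  rows <- list(dyn_record_row(state))
  snaps <- list()
  for (s in seq_len(nsteps)) {
    state <- dyn_time_step(state, dt, pulse)
    if (length(snapshot_times) &&
        any(abs(snapshot_times - state$t) < dt / 2 + 1e-12)) {
      snaps[[length(snaps) + 1L]] <-
        list(basis = state$basis, C = state$C, traj = state$traj, t = state$t)
    }
    if (s %% stride == 0L || s == nsteps)
      rows[[length(rows) + 1L]] <- dyn_record_row(state)
  }
  series <- do.call(rbind, rows)
  class(series) <- c("observable_series", class(series))
  list(series = series, state = state, snapshots = snaps)
}

dyn_record_row <- function(state) {
  basis <- state$basis
  ops <- c(list(mu = dipole_matrix(basis, state$model)),
           block_position_matrices(basis))
  S <- state$cache$S
  if (is.null(S)) S <- overlap_matrix(basis)
  record_icwf_row(state$t, state$C, S, ops)
}
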