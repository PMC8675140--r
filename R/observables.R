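#' Operator descriptor for expectation values
#'
#' A sum of one-body and pairwise terms (the same algebra as the
#' Hamiltonian): `one_body` is a list (per block) of vectorized coordinate
#' functions or NULL; `pairs` a list of `list(i, j, f)`.
#'
#' @param one_body list of functions `f(X)` per block (or NULL entries);
#' @param pairs list of pair terms.
#' @export
operator_descriptor <- function(one_body = NULL, pairs = list()) {
  structure(list(one_body = one_body, pairs = pairs), class = "operator_descriptor")
}

#' Expectation value of an operator
#'
#' For [grid_wavefunction()]s by direct quadrature; for ICWF states by the
#' factorized matrix elements \eqn{C^\dagger O C / C^\dagger S C}.
#'
#' @param state a `grid_wavefunction` or an `icwf_state`; @param op an
#'   [operator_descriptor()]; @param model the model (needed to locate blocks
#'   for grid states).
#' @export
expectation <- function(state, op, model = NULL) {
  UseMethod("expectation")
}

#' @export
expectation.grid_wavefunction <- function(state, op, model = NULL) {
  grid <- state$grid
  dims <- grid$n
  O <- array(0, dim = dims)
  if (!is.null(op$one_body)) {
    for (b in seq_along(op$one_body)) {
      f <- op$one_body[[b]]
      if (is.null(f)) next
      vals <- f(block_coords(grid, b))
      O <- O + expand_subset_array(array(vals, dims[axes_of_block(grid, b)]),
                                   axes_of_block(grid, b), dims)
    }
  }
  for (p in op$pairs) {
    ai <- axes_of_block(grid, p$i); aj <- axes_of_block(grid, p$j)
    Xi <- block_coords(grid, p$i); Xj <- block_coords(grid, p$j)
    ni <- nrow(Xi); nj <- nrow(Xj)
    vals <- p$f(Xi[rep(seq_len(ni), times = nj), , drop = FALSE],
                Xj[rep(seq_len(nj), each = ni), , drop = FALSE])
    sub <- c(ai, aj)
    A <- array(vals, dim = dims[sub])
    if (any(diff(sub) < 0)) { o <- order(sub); A <- aperm(A, o); sub <- sub[o] }
    O <- O + expand_subset_array(A, sub, dims)
  }
  dens <- Mod(state$psi)^2
  sum(O * dens) / sum(dens)
}

#' @export
expectation.icwf_state <- function(state, op, model = NULL) {
  basis <- state$basis
  grid <- basis$grid
  ob <- NULL
  if (!is.null(op$one_body)) {
    ob <- lapply(seq_along(basis$psis), function(i) {
      f <- op$one_body[[i]]
      if (is.null(f)) NULL else f(block_coords(grid, i))
    })
  }
  ps <- if (length(op$pairs))
    pair_kernel_svds(list(pairs = op$pairs), grid, rtol = 1e-13) else list()
  O <- operator_matrix(basis, one_body = ob, pair_svds = ps)
  S <- overlap_matrix(basis)
  Re(sum(Conj(state$C) * (O %*% state$C)) / sum(Conj(state$C) * (S %*% state$C)))
}

#' Reduced density on one block
#'
#' The marginal \eqn{|\Psi|^2} on a block's axes, integrated over all other
#' blocks, scaled by `particles` (e.g. 2 for the one-electron density of a
#' two-electron system, so that it integrates to the particle count).
#'
#' @param state a `grid_wavefunction` or `icwf_state`; @param block block
#'   index; @param particles normalization factor (default 1: integrates
#'   to 1).
#' @return list `density` (array over the block axes), `axes`.
#' @export
reduced_density <- function(state, block, particles = 1) {
  UseMethod("reduced_density")
}

#' @export
reduced_density.grid_wavefunction <- function(state, block, particles = 1) {
  grid <- state$grid
  keep <- axes_of_block(grid, block)
  dens <- Mod(state$psi)^2
  marg <- apply(dens, keep, sum)
  other_dv <- grid_dvol(grid) / block_dvol(grid, block)
  marg <- marg * other_dv
  tot <- sum(marg) * block_dvol(grid, block)
  list(density = particles * marg / tot, axes = grid$axes[keep])
}

#' @export
reduced_density.icwf_state <- function(state, block, particles = 1) {
  basis <- state$basis
  grid <- basis$grid
  C <- state$C
  Olist <- block_overlaps(basis)
  Wrest <- prod_except(Olist, block)            # Ncm x Ncm complementary overlaps
  P <- basis$psis[[block]]
  # rho(x) = sum_ab C*_a C_b conj(psi^a(x)) psi^b(x) Wrest_ab
  Mab <- (Conj(C) %o% C) * Wrest
  rho <- Re(rowSums((Conj(P) %*% Mab) * P))
  nrm <- sum(rho) * block_dvol(grid, block)
  list(density = array(particles * rho / nrm, dim = grid$n[axes_of_block(grid, block)]),
       axes = grid$axes[axes_of_block(grid, block)])
}

#' Delta-kick absorption spectrum
#'
#' The dipole-response spectrum of Yabana-Bertsch:
#' \eqn{S(\omega) \propto \omega\,\mathrm{Im}\int dt\, e^{i\omega t}
#' m(t)\,\Delta\mu(t)/\kappa}, with a mask \eqn{m(t) = \cos^2(\pi t/2T_f)}
#' that vanishes smoothly at the final time. Units are arbitrary; peak
#' positions and spacings are the physical content.
#'
#' @param series an observable data.frame with columns `time_au` and the
#'   dipole channel; @param kappa kick strength; @param channel dipole column
#'   name; @param pad zero-padding factor for frequency resolution; @param
#'   mask `"cos2"` or `"none"`.
#' @return data.frame of class `spectrum_result`: `omega_au`, `omega_ev`,
#'   `strength`.
#' @export
absorption_spectrum <- function(series, kappa, channel = "mu", pad = 8L,
                                mask = c("cos2", "none")) {
  mask <- match.arg(mask)
  t <- series$time_au
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1]) stop("non-uniform time grid")
  dt <- dt[1]
  if (kappa <= 0) stop("kappa must be positive")
  dmu <- series[[channel]] - series[[channel]][1]
  Tf <- t[length(t)] - t[1]
  m <- if (mask == "cos2") cos(pi * (t - t[1]) / (2 * Tf))^2 else rep(1, length(t))
  y <- dmu * m / kappa
  n <- length(y)
  npad <- pad * 2^ceiling(log2(n))
  Y <- fft(c(y, rep(0, npad - n)))
  # fft computes sum y_j exp(-2pi i jk/N); exp(+i w t) is its conjugate bin
  om <- 2 * pi * seq(0, npad - 1) / (npad * dt)
  keep <- om <= pi / dt
  # orientation chosen so that the response to the e^{+i kappa mu} kick is
  # a positive absorption line (checked on the kicked harmonic oscillator)
  S <- om * Im(Conj(Y)) * dt
  out <- data.frame(omega_au = om[keep], omega_ev = om[keep] * 27.211386,
                    strength = S[keep])
  class(out) <- c("spectrum_result", class(out))
  out
}

#' Local maxima of a spectrum
#'
#' @param spec a [absorption_spectrum()] result; @param threshold minimum
#'   height as a fraction of the global maximum; @param window frequency
#'   window `c(min, max)` in a.u.
#' @return data.frame `omega_au`, `strength`, ordered by frequency.
#' @export
spectrum_peaks <- function(spec, threshold = 0.05, window = NULL) {
  s <- spec$strength; om <- spec$omega_au
  if (!is.null(window)) {
    keep <- om >= window[1] & om <= window[2]
    s <- s[keep]; om <- om[keep]
  }
  n <- length(s)
  loc <- which(s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n]) + 1L
  loc <- loc[s[loc] >= threshold * max(s)]
  data.frame(omega_au = om[loc], strength = s[loc])
}

#' Adiabatic (Born-Oppenheimer) electronic-state populations
#'
#' \eqn{P_n(t) = \int dR\, |\langle\Phi^n(\cdot;R)|\Psi(t)\rangle_{elec}|^2}
#' by projection on the electronic eigenstates stored in a [compute_bopes()]
#' table (computed on the same electronic grid). The remainder
#' \eqn{1 - \sum_n P_n} lives in higher states.
#'
#' @param wf full [grid_wavefunction()]; @param bopes a `bopes_table` with
#'   `states` kept, whose `Rvals` match the nuclear grid of `wf`; @param
#'   model the model; @param n_states how many populations.
#' @return list `P` (vector), `chi` (nuclear amplitudes per state, matrix
#'   nR x n_states).
#' @export
adiabatic_populations <- function(wf, bopes, model, n_states = bopes$k) {
  prj <- project_on_bopes(wf, bopes, n_states)
  P <- colSums(Mod(prj$chi)^2) * prj$dR
  if (sum(P) > 1 + 1e-6) stop("populations exceed 1: grid mismatch?")
  list(P = P, chi = prj$chi)
}

# <Phi^n(.;R) | Psi(., R)>_elec for every stored R
project_on_bopes <- function(wf, bopes, n_states) {
  grid <- wf$grid
  nb <- bopes$nuclear_block
  nuc_axes <- axes_of_block(grid, nb)
  elec_axes <- setdiff(seq_len(grid$dims), nuc_axes)
  stopifnot(all(elec_axes < min(nuc_axes))) # electronic axes lead
  nE <- prod(grid$n[elec_axes]); nN <- prod(grid$n[nuc_axes])
  if (nrow(bopes$Rvals) != nN)
    stop("BOPES table must be tabulated on the nuclear grid of the state")
  dvE <- prod(vapply(grid$axes[elec_axes], function(a) a$dx, numeric(1)))
  dR <- grid_dvol(grid) / dvE
  Psi <- matrix(wf$psi, nrow = nE)
  chi <- matrix(0 + 0i, nN, n_states)
  for (r in seq_len(nN)) {
    chi[r, ] <- crossprod(Conj(bopes$states[[r]][, seq_len(n_states), drop = FALSE]),
                          Psi[, r]) * dvE
  }
  list(chi = chi, dR = dR)
}

#' Decoherence indicator between two adiabatic states
#'
#' The overlap of the nuclear probability densities attached to two
#' electronic surfaces,
#' \eqn{D_{nm}(t) = \int dR\, |\chi_n(R,t)|^2 |\chi_m(R,t)|^2} with
#' \eqn{\chi_n = \langle\Phi^n|\Psi\rangle_{elec}}: zero once the nuclear
#' packets on the two surfaces no longer overlap, transiently large while a
#' coherent superposition rides through a coupling region.
#'
#' @param wf full [grid_wavefunction()]; @param bopes a `bopes_table` with
#'   states; @param model the model; @param n,m surface indices (1-based).
#' @export
decoherence_indicator <- function(wf, bopes, model, n = 1L, m = 2L) {
  prj <- project_on_bopes(wf, bopes, max(n, m))
  sum(Mod(prj$chi[, n])^2 * Mod(prj$chi[, m])^2) * prj$dR
}

#' Write an observable series to CSV
#' @param series observable data.frame; @param path output file.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a wavefunction checkpoint
#'
#' Axes, amplitudes and metadata in a single RDS file (portable across
#' platforms; amplitudes stored as real/imaginary parts).
#'
#' @param wf a [grid_wavefunction()]; @param path file path; @param meta
#'   named list of extra metadata.
#' @export
save_checkpoint <- function(wf, path, meta = list()) {
  obj <- list(axes = lapply(wf$grid$axes, function(a) c(a$min, a$max, a$n)),
              axis_block = wf$grid$axis_block,
              blocks = wf$grid$blocks,
              re = Re(wf$psi), im = Im(wf$psi), time = wf$time,
              norm = wf_norm(wf), meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  axes <- lapply(obj$axes, function(a) grid_axis(a[1], a[2], a[3]))
  grid <- structure(list(axes = axes, axis_block = obj$axis_block,
                         blocks = obj$blocks,
                         n = vapply(axes, function(a) a$n, integer(1)),
                         dims = length(axes)),
                    class = "cwf_grid")
  grid_wavefunction(grid, obj$re + 1i * obj$im, time = obj$time,
                    normalize = FALSE)
}
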