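#' Imaginary-time ICWF eigensolver
#'
#' Solves the projected imaginary-time flow of the static-basis ansatz,
#' \deqn{dC/d\tau = -S^+ (H - E(\tau) S)\,C,}
#' with per-step renormalization (the running Rayleigh quotient
#' \eqn{E(\tau)} stabilizes the norm) and deflation of converged states by
#' S-orthogonalization. The flow is linear for a fixed basis, so by default
#' it is integrated exactly in the eigenbasis of the Hermitian pencil
#' \eqn{(H, S)} restricted to the numerical range of S (`integrator =
#' "exact"`); the explicit Euler stepper (`"euler"`) integrates the same flow
#' step by step and is retained for cross-validation and for the
#' renormalization variant of the algorithm.
#'
#' @param basis a `cwf_basis`; @param model the model; @param k_states number
#'   of states; @param dtau imaginary-time step (Euler path and trace
#'   spacing); @param tol energy convergence tolerance; @param rcond
#'   pseudo-inverse cutoff for S; @param max_iter Euler iteration cap;
#' @param integrator `"exact"` or `"euler"`; @param C0 deterministic start
#'   coefficients (default: uniform vector); @param S,H optionally
#'   precomputed matrices.
#' @return list: `energies` (ascending Rayleigh energies), `coefficients`
#'   (list of vectors, S-normalized), `traces` (list of energy-vs-tau
#'   data.frames of the started flow), `rank` (effective rank of S), `S`,
#'   `H`.
#' @export
imag_time_solve <- function(basis, model, k_states = 1L, dtau = 0.05,
                            tol = 1e-10, rcond = 1e-8, max_iter = 100000L,
                            integrator = c("exact", "euler"), C0 = NULL,
                            S = NULL, H = NULL) {
  integrator <- match.arg(integrator)
  if (is.null(S)) S <- overlap_matrix(basis)
  if (is.null(H)) H <- hamiltonian_matrix(basis, model)
  fac <- pinv_factor(S, rcond)
  if (fac$rank < nrow(S))
    warning(sprintf("overlap matrix rank-deficient: effective rank %d of %d",
                    fac$rank, nrow(S)))
  if (k_states > fac$rank) stop("k_states exceeds the effective rank")
  Ncm <- nrow(S)
  if (is.null(C0)) C0 <- rep(1 + 0i, Ncm)
  if (integrator == "exact") {
    # Hermitian pencil in the range of S: A = D^{-1/2} U' H U D^{-1/2}
    X <- sweep(fac$U, 2, sqrt(fac$d), "/")
    A <- crossprod(Conj(X), H %*% X)
    A <- (A + Conj(t(A))) / 2
    ed <- eigen(A, symmetric = TRUE)
    ord <- order(ed$values)
    energies <- ed$values[ord][seq_len(k_states)]
    Cs <- lapply(seq_len(k_states), function(g) {
      C <- as.vector(X %*% ed$vectors[, ord[g]])
      C / sqrt(Re(sum(Conj(C) * (S %*% C))))
    })
    # energy-vs-tau trace of the flow started from C0 (deflated per state):
    # y(tau) = exp(-Lambda tau) y0 in the pencil eigenbasis
    y0 <- as.vector(crossprod(Conj(ed$vectors), sqrt(fac$d) *
                                crossprod(Conj(fac$U), C0)))
    y0 <- y0[ord]
    lam <- ed$values[ord]
    traces <- vector("list", k_states)
    for (g in seq_len(k_states)) {
      y <- y0
      if (g > 1) y[seq_len(g - 1L)] <- 0 # deflation removes lower states
      if (sum(Mod(y)^2) < 1e-28) y[g] <- 1
      taus <- seq(0, by = dtau * 25, length.out = 200L)
      Etr <- vapply(taus, function(tt) {
        w <- Mod(y)^2 * exp(-2 * (lam - lam[g]) * tt)
        sum(w * lam) / sum(w)
      }, numeric(1))
      keep <- c(TRUE, abs(diff(Etr)) > 0)
      traces[[g]] <- data.frame(tau = taus, energy = Etr)[keep, ]
    }
    return(list(energies = energies, coefficients = Cs, traces = traces,
                rank = fac$rank, S = S, H = H))
  }
  # explicit Euler with renormalization and step halving
  energies <- numeric(0); Cs <- list(); traces <- list()
  snorm <- function(C) sqrt(Re(sum(Conj(C) * (S %*% C))))
  deflate <- function(C) {
    for (Cz in Cs) C <- C - Cz * sum(Conj(Cz) * (S %*% C))
    C
  }
  for (g in seq_len(k_states)) {
    # a generic (seeded) start for excited states: the deterministic uniform
    # vector can be near-orthogonal to a target state by symmetry
    C <- if (g == 1L) deflate(C0 + 0i)
    else deflate(local_runif(Ncm, seed = 33L + g) - 0.5 + 0i)
    if (snorm(C) < 1e-12) C <- deflate(local_runif(Ncm, seed = 77L + g) + 0i)
    C <- C / snorm(C)
    h <- dtau
    rq <- function(C) Re(sum(Conj(C) * (H %*% C)) / sum(Conj(C) * (S %*% C)))
    E <- rq(C); tr_tau <- 0; tr <- list(data.frame(tau = 0, energy = E))
    tau <- 0
    for (it in seq_len(max_iter)) {
      grad <- as.vector(pinv_apply(fac, H %*% C)) - E * C
      Cn <- deflate(C - h * grad)
      Cn <- Cn / snorm(Cn)
      En <- rq(Cn)
      if (En > E + 1e-12) { h <- h / 2; if (h < dtau / 1024) break; next }
      C <- Cn; tau <- tau + h
      conv <- abs(En - E) < tol * max(1, abs(En)) * (h / dtau)
      E <- En
      if (it %% 25L == 0L || conv) {
        tr[[length(tr) + 1L]] <- data.frame(tau = tau, energy = E)
      }
      if (conv && it > 10L) break
    }
    energies[g] <- E
    Cs[[g]] <- C
    traces[[g]] <- do.call(rbind, tr)
  }
  list(energies = energies, coefficients = Cs, traces = traces,
       rank = fac$rank, S = S, H = H)
}

#' Initialize a static-basis ICWF state for real-time propagation
#'
#' Bundles the basis, coefficients and cached matrices (overlap, field-free
#' Hamiltonian, dipole, pseudo-inverse factorization).
#'
#' @param basis a `cwf_basis`; @param model model; @param C coefficient
#'   vector (e.g. the ground state from [imag_time_solve()]); @param t0
#'   initial time; @param rcond pseudo-inverse cutoff; @param S,H optionally
#'   precomputed.
#' @return object of class `icwf_state` (mode `"sta"`).
#' @export
icwf_state <- function(basis, model, C, t0 = 0, rcond = 1e-8,
                       S = NULL, H = NULL) {
  if (is.null(S)) S <- overlap_matrix(basis)
  if (is.null(H)) H <- hamiltonian_matrix(basis, model)
  fac <- pinv_factor(S, rcond)
  structure(list(basis = basis, model = model, C = as.vector(C), t = t0,
                 S = S, H0 = H, D = dipole_matrix(basis, model),
                 fac = fac, rcond = rcond, mode = "sta"),
            class = "icwf_state")
}

#' @export
print.icwf_state <- function(x, ...) {
  cat(sprintf("<icwf_state> mode %s, N_cM = %d, t = %.4g au, C'SC = %.8f\n",
              x$mode, length(x$C), x$t, Re(state_norm2(x))))
  invisible(x)
}

state_norm2 <- function(state) {
  Re(sum(Conj(state$C) * (state$S %*% state$C)))
}

#' One RK4 step of the static-basis real-time coefficient equation
#'
#' Advances \eqn{i\,dC/dt = S^+ H(t)\,C} by one classical Runge-Kutta step
#' with midpoint field values; the basis is untouched.
#'
#' @param state an `icwf_state` (mode `"sta"`); @param dt time step; @param
#'   pulse optional [laser_pulse()].
#' @export
sta_real_time_step <- function(state, dt, pulse = NULL) {
  stopifnot(state$mode == "sta")
  f <- function(C, t) {
    Ht_C <- state$H0 %*% C
    if (!is.null(pulse)) {
      E <- field_value(pulse, t)
      if (E != 0) Ht_C <- Ht_C - E * (state$D %*% C)
    }
    -1i * as.vector(pinv_apply(state$fac, Ht_C))
  }
  C <- state$C; t <- state$t
  k1 <- f(C, t)
  k2 <- f(C + dt / 2 * k1, t + dt / 2)
  k3 <- f(C + dt / 2 * k2, t + dt / 2)
  k4 <- f(C + dt * k3, t + dt)
  state$C <- C + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  state$t <- t + dt
  state
}

#' Apply a delta kick to a static-basis ICWF state
#'
#' The impulsive length-gauge kick \eqn{e^{i\kappa\mu}} multiplies each CWF
#' by the per-block phase factor; the kicked state is re-expanded in the
#' (unchanged) basis by a pseudo-inverse projection.
#'
#' @param state an `icwf_state`; @param kappa kick strength (a.u.).
#' @export
kick_state <- function(state, kappa) {
  basis <- state$basis; model <- state$model
  Ncm <- length(state$C)
  B <- matrix(1 + 0i, Ncm, Ncm)
  for (i in seq_along(basis$psis)) {
    Xi <- block_coords(basis$grid, i)
    mu_i <- as.vector(Xi %*% model$dipole[[i]])
    P <- basis$psis[[i]]
    B <- B * (crossprod(Conj(P), exp(1i * kappa * mu_i) * P) *
                block_dvol(basis$grid, i))
  }
  b <- B %*% state$C
  state$C <- as.vector(pinv_apply(state$fac, b))
  state
}

#' Real-time propagation of a static-basis ICWF state
#'
#' Propagates the coefficients over `[t0, t0 + Tmax]`, recording the norm
#' \eqn{C^\dagger S C}, the dipole and per-block mean positions. With
#' `method = "rk4"` the RK4 stepper is used (any field). With `method =
#' "spectral"` (field-free runs, e.g. after a delta kick) the linear
#' coefficient equation is integrated exactly in the eigenbasis of the
#' Hermitian pencil (H, S) -- the same dynamics without time-discretization
#' error.
#'
#' @param state an `icwf_state`; @param dt time step (also the output spacing
#'   of the spectral path); @param Tmax propagation length; @param pulse
#'   optional pulse (rk4 only); @param stride record every `stride` steps;
#' @param method `"rk4"` or `"spectral"`; @param extra_ops named list of
#'   extra operator matrices whose expectations are recorded.
#' @return list `series` (observable data.frame), `state` (final).
#' @export
sta_propagate <- function(state, dt, Tmax, pulse = NULL, stride = 1L,
                          method = c("rk4", "spectral"), extra_ops = list()) {
  method <- match.arg(method)
  basis <- state$basis
  Xops <- block_position_matrices(basis)
  ops <- c(list(mu = state$D), Xops, extra_ops)
  if (method == "spectral") {
    if (!is.null(pulse) && pulse$E0 != 0)
      stop("spectral propagation requires a field-free Hamiltonian")
    fac <- state$fac
    X <- sweep(fac$U, 2, sqrt(fac$d), "/")
    A <- crossprod(Conj(X), state$H0 %*% X)
    A <- (A + Conj(t(A))) / 2
    ed <- eigen(A, symmetric = TRUE)
    Tm <- X %*% ed$vectors                       # Ncm x r map from y to C
    y0 <- as.vector(crossprod(Conj(ed$vectors),
                              sqrt(fac$d) * crossprod(Conj(fac$U), state$C)))
    times <- seq(0, Tmax, by = dt * stride)
    rows <- vector("list", length(times))
    for (q in seq_along(times)) {
      y <- exp(-1i * ed$values * times[q]) * y0
      C <- as.vector(Tm %*% y)
      rows[[q]] <- record_icwf_row(state$t + times[q], C, state$S, ops)
    }
    Cfin <- as.vector(Tm %*% (exp(-1i * ed$values * Tmax) * y0))
    state$C <- Cfin; state$t <- state$t + Tmax
    series <- do.call(rbind, rows)
    class(series) <- c("observable_series", class(series))
    return(list(series = series, state = state))
  }
  nsteps <- ceiling(Tmax / dt - 1e-12)
  rows <- list(record_icwf_row(state$t, state$C, state$S, ops))
  t_origin <- state$t
  for (s in seq_len(nsteps)) {
    state <- sta_real_time_step(state, dt, pulse)
    if (s %% stride == 0L || s == nsteps) {
      rows[[length(rows) + 1L]] <- record_icwf_row(state$t, state$C, state$S, ops)
    }
  }
  series <- do.call(rbind, rows)
  class(series) <- c("observable_series", class(series))
  list(series = series, state = state)
}

# per-axis position operator matrices named x1..xk
block_position_matrices <- function(basis) {
  grid <- basis$grid
  out <- list()
  for (a in seq_len(grid$dims)) {
    b <- grid$axis_block[a]
    ax_in_block <- which(axes_of_block(grid, b) == a)
    Xi <- block_coords(grid, b)
    ob <- vector("list", length(basis$psis))
    ob[[b]] <- Xi[, ax_in_block]
    out[[paste0("x", a)]] <- operator_matrix(basis, one_body = ob)
  }
  out
}

record_icwf_row <- function(t, C, S, ops) {
  n2 <- Re(sum(Conj(C) * (S %*% C)))
  row <- list(time_au = t, time_fs = t * 0.024188843, norm = sqrt(n2))
  for (nm in names(ops))
    row[[nm]] <- Re(sum(Conj(C) * (ops[[nm]] %*% C))) / n2
  as.data.frame(row)
}

#' Expectation value of the reconstructed ICWF wavefunction with its
#' label-swapped image
#'
#' For two identical 1D blocks, the overlap
#' \eqn{\langle\Psi|P_{12}\Psi\rangle / \langle\Psi|\Psi\rangle} measuring
#' spatial exchange symmetry of the ansatz.
#'
#' @param basis a `cwf_basis`; @param C coefficients; @param blocks the two
#'   identical block indices.
#' @export
swap_symmetry <- function(basis, C, blocks = c(1L, 2L)) {
  Olist <- block_overlaps(basis)
  i <- blocks[1]; j <- blocks[2]
  P_i <- basis$psis[[i]]; P_j <- basis$psis[[j]]
  Oij <- crossprod(Conj(P_i), P_j) * block_dvol(basis$grid, i)
  Oji <- crossprod(Conj(P_j), P_i) * block_dvol(basis$grid, j)
  Sswap <- Oij * Oji * prod_except(Olist, c(i, j))
  S <- prod_except(Olist, integer(0))
  Re(sum(Conj(C) * (Sswap %*% C)) / sum(Conj(C) * (S %*% C)))
}
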