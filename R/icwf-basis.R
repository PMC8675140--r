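#' Conditional one-body Hamiltonian
#'
#' \eqn{h_i^\alpha = K_i + W_i^\alpha(x_i)}: the kinetic operator of block `i`
#' plus every model term involving that block with all other blocks clamped
#' at the conditioning configuration (Hermitian by construction; the external
#' field enters through the block's dipole coupling).
#'
#' @param model,grid model and grid; @param block block index; @param point
#'   full configuration (one entry per axis); @param t time (for the field);
#' @param pulse optional [laser_pulse()]; @param order FD stencil order.
#' @return sparse symmetric matrix on the block's sub-grid.
#' @export
conditional_hamiltonian <- function(model, grid, block, point, t = 0,
                                    pulse = NULL, order = 4L) {
  field <- if (is.null(pulse)) 0 else field_value(pulse, t)
  block_kinetic_matrix(grid, block, order) +
    Matrix::Diagonal(x = conditional_potential_values(model, grid, block,
                                                      point, field))
}

#' Conditional-eigenstate basis (CWF basis)
#'
#' For every conditioning configuration \eqn{\lambda} and every block `i`,
#' the `M` lowest eigenstates of the conditional Hamiltonian
#' \eqn{h_i^\lambda}, arranged as columns \eqn{\alpha = \lambda + N_c(\nu-1)}
#' of one matrix per block. Column phases are fixed (first significant
#' component real-positive) and exact degeneracies are ordered by ascending
#' \eqn{\langle x\rangle}, then \eqn{\langle x^2\rangle}, so the basis is
#' reproducible across eigensolver backends.
#'
#' @param model,grid model and grid; @param ensemble a
#'   [sample_configurations()] result (its `configs` rows are the
#'   \eqn{x^\lambda}); @param M conditional excitations per configuration;
#' @param order FD stencil order; @param pair_rtol relative truncation for
#'   the pair-kernel SVD factorization cached on the basis.
#' @return object of class `cwf_basis`: `psis` (list per block of complex
#'   `n_i x N_cM` matrices, quadrature-normalized), `prov` (lambda, nu),
#'   `traj` (`N_cM x dims` conditioning/trajectory positions), `K` (cached
#'   kinetic matrices), `pair_svd`, `Nc`, `M`, `grid`.
#' @export
conditional_eigenbasis <- function(model, grid, ensemble, M = 1L, order = 4L,
                                   pair_rtol = 1e-12,
                                   kinetic_op = c("fd", "fft")) {
  kinetic_op <- match.arg(kinetic_op)
  X <- if (inherits(ensemble, "configuration_ensemble")) ensemble$configs
  else as.matrix(ensemble)
  Nc <- nrow(X); M <- as.integer(M)
  stopifnot(M >= 1L, ncol(X) == grid$dims)
  nb <- nrow(grid$blocks)
  Ncm <- Nc * M
  psis <- vector("list", nb)
  K <- lapply(seq_len(nb), function(i) block_kinetic_matrix(grid, i, order))
  for (i in seq_len(nb)) {
    ni <- block_npts(grid, i)
    P <- matrix(0 + 0i, ni, Ncm)
    dvb <- block_dvol(grid, i)
    Xi <- block_coords(grid, i)
    for (lam in seq_len(Nc)) {
      W <- conditional_potential_values(model, grid, i, X[lam, ])
      vec <- lowest_eigvecs(K[[i]], W, M)
      vec <- fix_eigvec_conventions(vec, Xi, dvb)
      for (nu in seq_len(M)) P[, lam + Nc * (nu - 1L)] <- vec$vectors[, nu]
    }
    psis[[i]] <- P
  }
  prov <- data.frame(lambda = rep(seq_len(Nc), times = M),
                     nu = rep(seq_len(M), each = Nc))
  traj <- X[prov$lambda, , drop = FALSE]
  kern <- pair_kernel_mats(model, grid)
  structure(list(psis = psis, prov = prov, traj = traj, K = K,
                 pair_svd = pair_kernel_svds(model, grid, pair_rtol, kern),
                 pair_kernel = kern, kinetic_op = kinetic_op,
                 Nc = Nc, M = M, grid = grid),
            class = "cwf_basis")
}

# apply the kinetic operator of block i to a matrix of CWF columns, using
# either the finite-difference matrix (consistent with sparse oracle
# eigensolves) or the spectral FFT operator (consistent with split-operator
# oracle propagation); matrix elements must share the discretization of the
# reference they are compared with
apply_block_kinetic <- function(basis, i, P) {
  if (identical(basis$kinetic_op, "fft")) {
    grid <- basis$grid
    ax <- axes_of_block(grid, i)
    m <- grid$blocks$mass[i]
    k2 <- lapply(grid$axes[ax], function(a) {
      kf <- 2 * pi / (a$n * a$dx) *
        c(0:floor(a$n / 2), -(ceiling(a$n / 2) - 1):-1)[1:a$n]
      kf^2 / (2 * m)
    })
    if (length(ax) == 1L)
      return(stats::mvfft(k2[[1]] * stats::mvfft(P), inverse = TRUE) / nrow(P))
    n1 <- grid$n[ax[1]]; n2 <- grid$n[ax[2]]
    K2 <- outer(k2[[1]], k2[[2]], `+`)
    out <- P
    for (c in seq_len(ncol(P))) {
      A <- matrix(P[, c], n1, n2)
      out[, c] <- as.vector(fft(K2 * fft(A), inverse = TRUE) / (n1 * n2))
    }
    return(out)
  }
  sp_cmult(basis$K[[i]], P)
}

#' @export
print.cwf_basis <- function(x, ...) {
  cat(sprintf("<cwf_basis> Nc = %d, M = %d (%d configurations) on %d blocks\n",
              x$Nc, x$M, x$Nc * x$M, length(x$psis)))
  invisible(x)
}

# M lowest eigenvectors of K + diag(W); dense for small blocks, shift-invert
# Lanczos otherwise; quadrature-normalized is handled by the caller
lowest_eigvecs <- function(K, W, M) {
  n <- nrow(K)
  if (n <= 700L) {
    H <- as.matrix(K) + diag(W, n, n)
    ed <- eigen(H, symmetric = TRUE)
    idx <- order(ed$values)[seq_len(M)]
    list(values = ed$values[idx], vectors = ed$vectors[, idx, drop = FALSE])
  } else {
    H <- K + Matrix::Diagonal(x = W)
    ed <- lanczos_shift_invert(H, k = M, sigma = min(W) - 0.1, tol = 1e-10)
    list(values = ed$values, vectors = ed$vectors)
  }
}

# deterministic phase + degenerate tie-breaks + quadrature normalization
fix_eigvec_conventions <- function(ed, Xi, dvb, degtol = 1e-10) {
  V <- ed$vectors; vals <- ed$values
  M <- ncol(V)
  if (M > 1) { # reorder exact degeneracies by <x>, then <x^2>
    grpstart <- 1L
    for (c in 2:(M + 1L)) {
      if (c > M || vals[c] - vals[grpstart] > degtol) {
        if (c - grpstart > 1L) {
          cols <- grpstart:(c - 1L)
          x1 <- vapply(cols, function(j) sum(Mod(V[, j])^2 * Xi[, 1]), numeric(1))
          x2 <- vapply(cols, function(j) sum(Mod(V[, j])^2 * Xi[, 1]^2), numeric(1))
          V[, cols] <- V[, cols[order(x1, x2)]]
        }
        grpstart <- c
      }
    }
  }
  for (c in seq_len(M)) {
    p <- which(abs(V[, c]) > 0.5 * max(abs(V[, c])))[1]
    if (Re(V[p, c]) < 0) V[, c] <- -V[, c]
  }
  list(values = vals, vectors = V / sqrt(dvb))
}

# raw pair-interaction kernel matrices on the block sub-grids
pair_kernel_mats <- function(model, grid) {
  lapply(model$pairs, function(p) {
    Xi <- block_coords(grid, p$i); Xj <- block_coords(grid, p$j)
    ni <- nrow(Xi); nj <- nrow(Xj)
    big_i <- Xi[rep(seq_len(ni), times = nj), , drop = FALSE]
    big_j <- Xj[rep(seq_len(nj), each = ni), , drop = FALSE]
    list(i = p$i, j = p$j, K = matrix(p$f(big_i, big_j), ni, nj))
  })
}

# SVD factorization of every pair-interaction kernel on the block sub-grids:
# kernel[x_i, x_j] ~ sum_s d_s u_s(x_i) v_s(x_j), truncated at rtol
pair_kernel_svds <- function(model, grid, rtol = 1e-12, kernels = NULL) {
  if (is.null(kernels)) kernels <- pair_kernel_mats(model, grid)
  lapply(kernels, function(p) {
    sv <- svd(p$K)
    keep <- which(sv$d > rtol * sv$d[1])
    list(i = p$i, j = p$j, d = sv$d[keep],
         u = sv$u[, keep, drop = FALSE], v = sv$v[, keep, drop = FALSE])
  })
}

# real sparse matrix times complex dense matrix (Matrix has no complex class)
sp_cmult <- function(K, P) {
  if (is.complex(P))
    as.matrix(K %*% Re(P)) + 1i * as.matrix(K %*% Im(P))
  else as.matrix(K %*% P)
}

# per-block overlap matrices O_i[alpha, beta] = <psi_i^a | psi_i^b>
block_overlaps <- function(basis) {
  lapply(seq_along(basis$psis), function(i)
    crossprod(Conj(basis$psis[[i]]), basis$psis[[i]]) *
      block_dvol(basis$grid, i))
}

# Hadamard product of all overlap matrices except those in `skip`
prod_except <- function(Olist, skip) {
  keep <- setdiff(seq_along(Olist), skip)
  if (length(keep) == 0L)
    return(matrix(1 + 0i, nrow(Olist[[1]]), ncol(Olist[[1]])))
  Reduce(`*`, Olist[keep])
}

#' Overlap matrix of the ICWF ansatz
#'
#' \eqn{S_{\alpha\beta} = \prod_i \langle\psi_i^\alpha|\psi_i^\beta\rangle}
#' (quadrature inner products). Hermitian with unit diagonal; positive
#' semidefinite as a Gram matrix.
#'
#' @param basis a `cwf_basis`.
#' @export
overlap_matrix <- function(basis) {
  S <- prod_except(block_overlaps(basis), integer(0))
  (S + Conj(t(S))) / 2
}

#' Matrix of a sum of one-body and pairwise operators in the ICWF basis
#'
#' The factorized matrix elements shared by the Hamiltonian, the dipole and
#' every expectation value: one-body terms weighted by the overlap product of
#' the remaining blocks, pair terms by 2D quadrature through the cached (or
#' supplied) kernel factorization.
#'
#' @param basis a `cwf_basis`; @param one_body list (per block) of potential
#'   value vectors on the block sub-grid, or NULL; @param pair_svds list of
#'   kernel factorizations as produced inside [conditional_eigenbasis()];
#' @param kinetic logical: include the kinetic operators; @param Olist
#'   optional precomputed [block_overlaps()].
#' @return `N_cM x N_cM` complex matrix.
#' @export
operator_matrix <- function(basis, one_body = NULL, pair_svds = list(),
                            kinetic = FALSE, Olist = NULL) {
  if (is.null(Olist)) Olist <- block_overlaps(basis)
  nb <- length(basis$psis)
  Ncm <- ncol(basis$psis[[1]])
  out <- matrix(0 + 0i, Ncm, Ncm)
  for (i in seq_len(nb)) {
    P <- basis$psis[[i]]
    dvb <- block_dvol(basis$grid, i)
    A <- NULL
    if (kinetic) A <- apply_block_kinetic(basis, i, P)
    if (!is.null(one_body) && !is.null(one_body[[i]])) {
      A <- if (is.null(A)) one_body[[i]] * P else A + one_body[[i]] * P
    }
    if (!is.null(A)) {
      h1 <- crossprod(Conj(P), A) * dvb
      out <- out + prod_except(Olist, i) * h1
    }
  }
  for (p in pair_svds) {
    Pi <- basis$psis[[p$i]]; Pj <- basis$psis[[p$j]]
    dvi <- block_dvol(basis$grid, p$i); dvj <- block_dvol(basis$grid, p$j)
    r <- length(p$d)
    acc <- matrix(0 + 0i, Ncm, Ncm)
    # BLAS-3 batches over SVD terms, chunked to bound the workspace
    rc <- max(1L, min(r, as.integer(8e6 / (Ncm * Ncm))))
    s0 <- 1L
    while (s0 <= r) {
      ss <- s0:min(r, s0 + rc - 1L); nc <- length(ss)
      UPi <- Pi[, rep(seq_len(Ncm), nc)] *
        p$u[, rep(ss, each = Ncm), drop = FALSE]
      A <- crossprod(Conj(Pi), UPi) * dvi          # Ncm x (Ncm*nc)
      UPi <- Pj[, rep(seq_len(Ncm), nc)] *
        p$v[, rep(ss, each = Ncm), drop = FALSE]
      B <- crossprod(Conj(Pj), UPi) * dvj
      for (q in seq_len(nc)) {
        cols <- ((q - 1L) * Ncm + 1L):(q * Ncm)
        acc <- acc + p$d[ss[q]] * (A[, cols] * B[, cols])
      }
      s0 <- s0 + rc
    }
    out <- out + prod_except(Olist, c(p$i, p$j)) * acc
  }
  out
}

#' Hamiltonian matrix of the ICWF ansatz
#'
#' \eqn{H_{\alpha\beta}}: kinetic and one-body terms weighted by the
#' complementary overlap products plus all pair interactions by 2D
#' quadrature. Hermitian for real potentials.
#'
#' @param basis a `cwf_basis`; @param model the model; @param t time; @param
#'   pulse optional [laser_pulse()] (length-gauge field at time `t`); @param
#'   Olist optional precomputed overlaps.
#' @export
hamiltonian_matrix <- function(basis, model, t = 0, pulse = NULL, Olist = NULL) {
  field <- if (is.null(pulse)) 0 else field_value(pulse, t)
  nb <- length(basis$psis)
  ob <- vector("list", nb)
  for (i in seq_len(nb)) {
    Xi <- block_coords(basis$grid, i)
    v <- if (is.null(model$one_body[[i]])) rep(0, nrow(Xi)) else model$one_body[[i]](Xi)
    if (field != 0) v <- v - field * as.vector(Xi %*% model$dipole[[i]])
    ob[[i]] <- v
  }
  H <- operator_matrix(basis, one_body = ob, pair_svds = basis$pair_svd,
                       kinetic = TRUE, Olist = Olist)
  if (is.null(pulse)) (H + Conj(t(H))) / 2 else H
}

#' Dipole-operator matrix in the ICWF basis
#' @param basis a `cwf_basis`; @param model the model.
#' @export
dipole_matrix <- function(basis, model) {
  nb <- length(basis$psis)
  ob <- lapply(seq_len(nb), function(i) {
    Xi <- block_coords(basis$grid, i)
    as.vector(Xi %*% model$dipole[[i]])
  })
  operator_matrix(basis, one_body = ob)
}

# conditional potentials of every trajectory as an n_i x Ncm matrix
# (vectorized over trajectories: one evaluation per pair term)
cond_pot_matrix <- function(model, grid, block, traj, t = 0, pulse = NULL) {
  field <- if (is.null(pulse)) 0 else field_value(pulse, t)
  nt <- nrow(traj)
  Xi <- block_coords(grid, block)
  ni <- nrow(Xi)
  v0 <- if (is.null(model$one_body[[block]])) rep(0, ni)
  else model$one_body[[block]](Xi)
  if (field != 0) v0 <- v0 - field * as.vector(Xi %*% model$dipole[[block]])
  out <- matrix(v0, ni, nt)
  Xrep <- Xi[rep(seq_len(ni), times = nt), , drop = FALSE]
  for (p in model$pairs) {
    if (p$i != block && p$j != block) next
    other <- if (p$i == block) p$j else p$i
    oax <- axes_of_block(grid, other)
    Xo <- traj[rep(seq_len(nt), each = ni), oax, drop = FALSE]
    vals <- if (p$i == block) p$f(Xrep, Xo) else p$f(Xo, Xrep)
    out <- out + matrix(vals, ni, nt)
  }
  out
}

# (sum over pair terms of the pair part of H) %*% C for a two-block basis:
# reconstruct Psi_C on the joint grid, weight by the kernel, contract back
pair_hamiltonian_matvec <- function(basis, C) {
  Pi1 <- basis$psis[[1]]; Pj <- basis$psis[[2]]
  dv <- block_dvol(basis$grid, 1) * block_dvol(basis$grid, 2)
  PsiC <- Pi1 %*% (C * t(Pj))
  out <- 0
  for (p in basis$pair_kernel) {
    B <- if (p$i == 1L) p$K * PsiC else t(p$K) * PsiC
    Tm <- crossprod(Conj(Pi1), B)
    out <- out + rowSums(Tm * t(Conj(Pj))) * dv
  }
  out
}

#' Coupling matrix of the dyn-ICWF coefficient equation
#'
#' \eqn{G_{\alpha\beta} = \sum_i \prod_{j\ne i}
#' \langle\psi_j^\alpha|\psi_j^\beta\rangle \,
#' \langle\psi_i^\alpha| h_i^\beta |\psi_i^\beta\rangle}: the conditional
#' one-body generators acting on the ket's CWFs. Not Hermitian in general
#' (the generator follows the ket column); its one-body kinetic content
#' cancels against the Hamiltonian matrix in the coefficient equation.
#'
#' @param basis a `cwf_basis`; @param model the model; @param traj trajectory
#'   matrix (`N_cM x dims`); @param t time; @param pulse optional pulse;
#' @param Olist optional precomputed overlaps; @param Wmats optional
#'   precomputed conditional-potential matrices per block.
#' @export
coupling_matrix <- function(basis, model, traj, t = 0, pulse = NULL,
                            Olist = NULL, Wmats = NULL) {
  if (is.null(Olist)) Olist <- block_overlaps(basis)
  nb <- length(basis$psis)
  Ncm <- ncol(basis$psis[[1]])
  G <- matrix(0 + 0i, Ncm, Ncm)
  Eb <- numeric(Ncm)
  for (i in seq_len(nb)) {
    P <- basis$psis[[i]]
    W <- if (is.null(Wmats)) cond_pot_matrix(model, basis$grid, i, traj, t, pulse)
    else Wmats[[i]]
    Phi <- apply_block_kinetic(basis, i, P) + W * P
    Mi <- crossprod(Conj(P), Phi) * block_dvol(basis$grid, i)
    G <- G + prod_except(Olist, i) * Mi
    Eb <- Eb + Re(diag(Mi))
  }
  # per-ket total conditional energies, used by the dyn propagator's energy
  # gauge (each CWF carries e^{+i e t}; the coefficient equation compensates)
  attr(G, "ket_energy") <- Eb
  G
}

#' Pseudo-inverse factorization of an overlap matrix
#'
#' Eigendecomposition-based Moore-Penrose pseudo-inverse of a Hermitian PSD
#' overlap, with relative cutoff `rcond`; reports the effective rank.
#'
#' @param S Hermitian PSD matrix; @param rcond relative eigenvalue cutoff.
#' @return list `U` (kept eigenvectors), `d` (kept eigenvalues), `rank`.
#' @export
pinv_factor <- function(S, rcond = 1e-8) {
  ed <- eigen((S + Conj(t(S))) / 2, symmetric = TRUE)
  keep <- ed$values > rcond * max(ed$values, 0)
  list(U = ed$vectors[, keep, drop = FALSE], d = ed$values[keep],
       rank = sum(keep), n = nrow(S))
}

#' Apply a pseudo-inverse factorization to a vector (or matrix)
#' @param fac a [pinv_factor()]; @param v vector or matrix.
#' @export
pinv_apply <- function(fac, v) {
  fac$U %*% (crossprod(Conj(fac$U), v) / fac$d)
}

#' Moore-Penrose pseudo-inverse application
#'
#' One-shot convenience wrapper around [pinv_factor()] + [pinv_apply()];
#' also returns the effective rank.
#'
#' @param S Hermitian PSD matrix; @param v vector; @param rcond cutoff.
#' @return list `x` (the solution), `rank`.
#' @export
pseudo_inverse_apply <- function(S, v, rcond = 1e-8) {
  fac <- pinv_factor(S, rcond)
  list(x = as.vector(pinv_apply(fac, v)), rank = fac$rank)
}
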