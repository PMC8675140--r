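#' Lanczos eigensolver for the lowest eigenpairs
#'
#' Lanczos with full reorthogonalization and adaptive Krylov growth. The
#' workhorse behind every sparse grid eigensolve in the package (there is no
#' iterative sparse eigensolver in base R or Matrix).
#'
#' @param A sparse symmetric matrix, or a matvec `function(v)`.
#' @param n problem size (required when `A` is a function).
#' @param k number of lowest eigenpairs.
#' @param v0 start vector (default: seeded pseudo-random, deterministic).
#' @param m initial Krylov size; grown until residuals converge.
#' @param tol relative residual tolerance.
#' @param mmax hard cap on the Krylov size.
#' @return list with `values` (ascending), `vectors` (n x k, orthonormal),
#'   `residuals`, `iterations`.
#' @export
lanczos_lowest <- function(A, k = 1, n = NULL, v0 = NULL, m = NULL,
                           tol = 1e-9, mmax = NULL) {
  matvec <- if (is.function(A)) A else function(v) as.vector(A %*% v)
  if (is.null(n)) {
    if (is.function(A)) stop("n required with a matvec function")
    n <- nrow(A)
  }
  if (is.null(m)) m <- min(n, max(4L * k + 40L, 60L))
  if (is.null(mmax)) mmax <- min(n, max(40L * k + 200L, 600L))
  if (is.null(v0)) v0 <- local_runif(n, seed = 20211109L) - 0.5
  v0 <- v0 / sqrt(sum(v0^2))
  V <- matrix(0, n, m)
  alpha <- numeric(0); beta <- numeric(0)
  V[, 1] <- v0
  j <- 0L
  prev_vals <- NULL
  repeat {
    j <- j + 1L
    w <- matvec(V[, j])
    a <- sum(V[, j] * w)
    alpha[j] <- a
    w <- w - a * V[, j]
    if (j > 1L) w <- w - beta[j - 1L] * V[, j - 1L]
    # full reorthogonalization (twice is enough)
    for (rep in 1:2) w <- w - V[, 1:j, drop = FALSE] %*%
        crossprod(V[, 1:j, drop = FALSE], w)
    b <- sqrt(sum(w^2))
    check <- (j %% 20L == 0L) || j == mmax || j == n || b < 1e-13
    if (check && j >= max(2L * k, 10L)) {
      Tj <- diag(alpha, j, j)
      if (j > 1) {
        Tj[cbind(1:(j - 1), 2:j)] <- beta[1:(j - 1)]
        Tj[cbind(2:j, 1:(j - 1))] <- beta[1:(j - 1)]
      }
      ed <- eigen(Tj, symmetric = TRUE)
      idx <- order(ed$values)[1:k]
      res <- abs(b * ed$vectors[j, idx])
      scale <- pmax(abs(ed$values[idx]), 1)
      # residuals alone can accept an incomplete set when an interior
      # (near-degenerate) state has not yet entered the Krylov space; also
      # require the k lowest Ritz values to have stabilized between checks
      stable <- !is.null(prev_vals) &&
        max(abs(ed$values[idx] - prev_vals)) < 10 * tol * max(scale)
      prev_vals <- ed$values[idx]
      if ((all(res < tol * scale) && stable) ||
          j >= mmax || j >= n || b < 1e-13) {
        vec <- V[, 1:j, drop = FALSE] %*% ed$vectors[, idx, drop = FALSE]
        # re-orthonormalize for safety
        qr_ <- qr(vec)
        vec <- qr.Q(qr_)
        # fix global sign: largest-magnitude component positive
        for (c in seq_len(ncol(vec))) {
          p <- which.max(abs(vec[, c]))
          if (vec[p, c] < 0) vec[, c] <- -vec[, c]
        }
        if (!all(res < tol * scale) && b >= 1e-13 && j >= mmax)
          warning(sprintf("Lanczos: max residual %.2e after %d iterations",
                          max(res), j))
        return(list(values = ed$values[idx], vectors = vec,
                    residuals = res, iterations = j))
      }
    }
    if (j == m) { # grow the basis
      m <- min(mmax, n, 2L * m)
      V2 <- matrix(0, n, m); V2[, 1:j] <- V[, 1:j]; V <- V2
    }
    if (b < 1e-13) { # invariant subspace: restart with a fresh direction
      w <- local_runif(n, seed = 7L + j) - 0.5
      for (rep in 1:2) w <- w - V[, 1:j, drop = FALSE] %*%
          crossprod(V[, 1:j, drop = FALSE], w)
      b <- sqrt(sum(w^2))
    }
    beta[j] <- b
    V[, j + 1L] <- w / b
  }
}

# deterministic uniforms that do not disturb the global RNG stream
local_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  stats::runif(n)
}

#' Shift-invert Lanczos for the lowest eigenpairs of a sparse matrix
#'
#' Factorizes `H - sigma I` once (sparse LU) and runs Lanczos on the inverse,
#' which converges in a few dozen iterations even when the spectrum spans
#' orders of magnitude more than the level spacing (heavy nuclear
#' coordinates). When `sigma` is NULL a cheap plain-Lanczos pass estimates the
#' lower spectral edge first.
#'
#' @param H sparse symmetric matrix; @param k number of lowest states; @param
#'   sigma spectral shift (must be below the ground energy for reliability);
#' @param tol residual tolerance on the original problem.
#' @return as [lanczos_lowest()].
#' @export
lanczos_shift_invert <- function(H, k = 1, sigma = NULL, tol = 1e-9) {
  n <- nrow(H)
  if (is.null(sigma)) {
    rough <- lanczos_lowest(H, k = min(k + 1L, 4L), n = n, tol = 1e-2,
                            m = 60L, mmax = 150L)
    spread <- max(diff(rough$values), 0.05)
    sigma <- rough$values[1] - max(0.1, spread)
  }
  A <- H - Matrix::Diagonal(n, sigma)
  lu <- Matrix::lu(methods::as(A, "CsparseMatrix"))
  matvec <- function(v) as.vector(Matrix::solve(lu, v))
  # largest eigenvalues of the inverse = lowest of H; Lanczos finds extremal
  # ends, so solve for the k largest of -A^{-1} ... equivalently run on
  # A^{-1} and take the k largest Ritz values.
  ed <- lanczos_largest(matvec, n, k, tol = tol)
  vals <- sigma + 1 / ed$values
  o <- order(vals)
  vec <- ed$vectors[, o, drop = FALSE]
  # Rayleigh quotients on H for accurate eigenvalues
  vals <- vapply(seq_len(k), function(j) {
    v <- vec[, j]; sum(v * as.vector(H %*% v))
  }, numeric(1))
  resid <- vapply(seq_len(k), function(j) {
    v <- vec[, j]; sqrt(sum((as.vector(H %*% v) - vals[j] * v)^2))
  }, numeric(1))
  list(values = vals, vectors = vec, residuals = resid,
       iterations = ed$iterations, sigma = sigma)
}

# Lanczos for the k algebraically largest eigenpairs of a matvec
lanczos_largest <- function(matvec, n, k, tol = 1e-9, m = NULL, mmax = 400L) {
  neg <- function(v) -matvec(v)
  ed <- lanczos_lowest(neg, k = k, n = n, tol = tol, m = m, mmax = mmax)
  list(values = -ed$values, vectors = ed$vectors, iterations = ed$iterations)
}

#' Exact eigenstates of a model on a grid
#'
#' Sparse diagonalization of the full finite-difference Hamiltonian. Method
#' selection is automatic: plain Lanczos for small problems, shift-invert
#' Lanczos (sparse LU) for one- and two-axis grids, imaginary-time
#' propagation with deflation beyond 2e6 points where no factorization or
#' Krylov basis fits.
#'
#' @param model a `cwf_model`; @param grid a `cwf_grid`; @param k number of
#'   lowest states; @param order FD stencil order; @param tol residual
#'   tolerance; @param v0 optional start vector; @param method one of
#'   "auto", "lanczos", "shift-invert", "imag".
#' @return list with `energies` (ascending) and `states` (list of
#'   [grid_wavefunction()]s, orthonormal).
#' @export
exact_eigenstates <- function(model, grid, k = 1, order = 4L, tol = 1e-9,
                              v0 = NULL, method = "auto") {
  N <- prod(as.numeric(grid$n))
  if (method == "auto") {
    method <- if (N > 2e6) "imag"
    else if (N <= 700) "dense"
    else if (grid$dims <= 2 && N > 3000) "shift-invert"
    else "lanczos"
  }
  if (method == "imag") {
    it <- imag_time_states(model, grid, k = k)
    return(list(energies = it$energies, states = it$states,
                residuals = rep(NA_real_, k)))
  }
  if (N > 1e7) stop("grid too large for direct eigensolve (> 1e7 points)")
  H <- hamiltonian_sparse(model, grid, order = order)
  ed <- if (method == "dense") {
    dd <- eigen(as.matrix(H), symmetric = TRUE)
    idx <- order(dd$values)[seq_len(k)]
    vec <- dd$vectors[, idx, drop = FALSE]
    for (c in seq_len(k)) {
      p <- which.max(abs(vec[, c]))
      if (vec[p, c] < 0) vec[, c] <- -vec[, c]
    }
    list(values = dd$values[idx], vectors = vec,
         residuals = rep(0, k))
  } else if (method == "shift-invert") {
    # the potential minimum bounds E0 from below: a safe, free shift
    sigma <- min(potential_array(model, grid)) - 0.1
    lanczos_shift_invert(H, k = k, sigma = sigma, tol = tol)
  } else lanczos_lowest(H, k = k, n = nrow(H), tol = tol, v0 = v0)
  dv <- grid_dvol(grid)
  states <- lapply(seq_len(k), function(j)
    grid_wavefunction(grid, array(ed$vectors[, j] / sqrt(dv), dim = grid$n),
                      normalize = FALSE))
  list(energies = ed$values, states = states, residuals = ed$residuals)
}

# apply a per-axis operator M along axis a of an array
apply_axis_operator <- function(arr, M, a) {
  dims <- dim(arr); k <- length(dims)
  perm <- c(a, setdiff(seq_len(k), a))
  tmp <- aperm(arr, perm)
  sh <- dim(tmp)
  tmp <- matrix(tmp, nrow = dims[a])
  tmp <- sp_cmult(M, tmp)
  tmp <- array(tmp, dim = sh)
  aperm(tmp, order(perm))
}

# kinetic phase/decay array for split-operator steps:
# sum over axes of k^2/(2 m_axis) on the FFT frequency grid
kinetic_k2_array <- function(grid) {
  dims <- grid$n
  parts <- lapply(seq_len(grid$dims), function(a) {
    n <- dims[a]; dx <- grid$axes[[a]]$dx
    kf <- 2 * pi / (n * dx) * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    kf^2 / (2 * grid$blocks$mass[grid$axis_block[a]])
  })
  out <- array(0, dim = dims)
  for (a in seq_along(parts)) out <- out + axis_vector_array(parts[[a]], a, dims)
  out
}

#' Split-operator (Strang) propagation of the time-dependent Schroedinger
#' equation
#'
#' FFT-based kinetic step between two half potential steps; the external field
#' enters the potential in the length gauge at the midpoint time. Norm is
#' conserved to machine precision without a mask.
#'
#' @param model,grid model and grid; @param psi0 initial [grid_wavefunction()];
#' @param dt time step (a.u.); @param Tmax final time; @param pulse optional
#'   [laser_pulse()]; @param mask optional absorbing-mask array (from
#'   [grid_mask()]); @param stride record observables every `stride` steps;
#' @param extra named list of functions `f(psi, grid)` recorded as extra
#'   channels; @param snapshot_times times at which full wavefunction copies
#'   are kept; @param autocorr record `|<psi0|psi(t)>|`.
#' @return list with `series` (an observable data.frame: time, norm, dipole
#'   `mu`, per-axis positions), `psi` (final state), `snapshots`.
#' @export
exact_propagate <- function(model, grid, psi0, dt, Tmax, pulse = NULL,
                            mask = NULL, stride = 10L, extra = list(),
                            snapshot_times = numeric(0), autocorr = FALSE) {
  psi <- psi0$psi
  dims <- grid$n; dv <- grid_dvol(grid)
  V0 <- potential_array(model, grid)
  D <- dipole_array(model, grid)
  K2 <- kinetic_k2_array(grid)
  Kphase <- exp(-1i * dt * K2)
  nsteps <- ceiling(Tmax / dt - 1e-12)
  xarr <- lapply(seq_len(grid$dims), function(a)
    axis_vector_array(grid$axes[[a]]$x, a, dims))
  has_field <- !is.null(pulse) && pulse$E0 != 0
  halfphase <- exp(-1i * dt / 2 * V0)
  rec <- list(); snaps <- list(); si <- 1L
  record <- function(t, psi) {
    dens <- Re(psi * Conj(psi))
    nrm2 <- sum(dens) * dv
    row <- list(time_au = t, time_fs = t * 0.024188843,
                norm = sqrt(nrm2),
                mu = sum(D * dens) * dv / nrm2)
    for (a in seq_len(grid$dims))
      row[[paste0("x", a)]] <- sum(xarr[[a]] * dens) * dv / nrm2
    if (autocorr) row$autocorr <- Mod(sum(Conj(psi0$psi) * psi) * dv)
    for (nm in names(extra)) row[[nm]] <- extra[[nm]](psi, grid)
    row
  }
  rec[[1]] <- record(psi0$time, psi)
  t <- psi0$time
  for (s in seq_len(nsteps)) {
    ph <- if (has_field) {
      Em <- field_value(pulse, t + dt / 2 - psi0$time)
      exp(-1i * dt / 2 * (V0 - Em * D))
    } else halfphase
    psi <- ph * psi
    psi <- fft(Kphase * fft(psi), inverse = TRUE) / length(psi)
    psi <- ph * psi
    if (!is.null(mask)) psi <- mask * psi
    t <- t + dt
    if (length(snapshot_times) &&
        any(abs(snapshot_times - t) < dt / 2 + 1e-12)) {
      snaps[[length(snaps) + 1L]] <-
        grid_wavefunction(grid, psi, time = t, normalize = FALSE)
    }
    if (s %% stride == 0L) {
      si <- si + 1L
      rec[[si]] <- record(t, psi)
      nr <- rec[[si]]$norm
      if (!is.finite(nr) || (is.null(mask) && nr > 1 + 1e-3))
        stop(sprintf("norm blow-up at t = %.3f (norm = %.3g); reduce dt", t, nr))
    }
  }
  series <- do.call(rbind, lapply(rec, function(r) as.data.frame(r)))
  class(series) <- c("observable_series", class(series))
  list(series = series,
       psi = grid_wavefunction(grid, psi, time = t, normalize = FALSE),
       snapshots = snaps)
}

#' Imaginary-time ground (and deflated excited) states by split-operator
#'
#' FFT imaginary-time propagation with per-step renormalization; excited
#' states by Gram-Schmidt deflation against the converged lower states.
#' Preferred over Lanczos for grids too large to hold a Krylov basis.
#'
#' @param model,grid model and grid; @param k number of states; @param dtau
#'   imaginary-time step; @param tol energy convergence tolerance; @param
#'   maxit iteration cap; @param psi0 optional start wavefunction.
#' @return list with `energies`, `states`.
#' @export
imag_time_states <- function(model, grid, k = 1, dtau = 0.05, tol = 1e-10,
                             maxit = 20000L, psi0 = NULL) {
  dims <- grid$n; dv <- grid_dvol(grid)
  V0 <- potential_array(model, grid)
  Kdec <- exp(-dtau * kinetic_k2_array(grid))
  halfV <- exp(-dtau / 2 * V0)
  if (is.null(psi0)) {
    i0 <- which.min(V0)
    idx <- arrayInd(i0, dims)
    g <- array(1, dims)
    for (a in seq_len(grid$dims)) {
      x <- grid$axes[[a]]$x
      g <- g * axis_vector_array(exp(-(x - x[idx[a]])^2 / 2), a, dims)
    }
    psi <- g + 1e-3 * array(local_runif(prod(dims), seed = 11L), dims)
  } else psi <- psi0$psi
  states <- list(); energies <- numeric(0)
  for (st in seq_len(k)) {
    if (st > 1) { # fresh deterministic start orthogonal to converged states
      psi <- array(local_runif(prod(dims), seed = 100L + st, ) - 0.5, dims)
    }
    Eold <- Inf
    for (it in seq_len(maxit)) {
      for (s in states) psi <- psi - sum(Conj(s) * psi) * dv * s
      psi <- halfV * psi
      psi <- fft(Kdec * fft(psi), inverse = TRUE) / length(psi)
      psi <- halfV * psi
      nrm <- sqrt(sum(Mod(psi)^2) * dv)
      E <- -log(nrm) / dtau
      psi <- psi / nrm
      if (it %% 10L == 0L) {
        if (abs(E - Eold) < tol) break
        Eold <- E
      }
    }
    for (s in states) psi <- psi - sum(Conj(s) * psi) * dv * s
    psi <- psi / sqrt(sum(Mod(psi)^2) * dv)
    states[[st]] <- psi
    # Rayleigh quotient on the FD Hamiltonian for a quadrature-consistent value
    energies[st] <- Re(grid_energy(model, grid, psi))
  }
  list(energies = energies,
       states = lapply(states, function(p)
         grid_wavefunction(grid, p, normalize = FALSE)))
}

#' Energy expectation of amplitudes on a grid (FFT kinetic + potential)
#' @keywords internal
grid_energy <- function(model, grid, psi, field = 0) {
  dv <- grid_dvol(grid)
  K2 <- kinetic_k2_array(grid)
  kin <- sum(Conj(psi) * (fft(K2 * fft(psi), inverse = TRUE) / length(psi))) * dv
  pot <- sum(potential_array(model, grid, field) * Mod(psi)^2) * dv
  Re(kin + pot) / (sum(Mod(psi)^2) * dv)
}

#' Born-Oppenheimer potential-energy surfaces
#'
#' Diagonalizes the clamped-nucleus electronic Hamiltonian at each nuclear
#' geometry. Surfaces include every term of the model evaluated at the clamped
#' geometry (in particular nuclear-nuclear repulsion), so that the nuclear
#' Schroedinger equation on a surface needs no extra terms.
#'
#' @param model a `cwf_model`; @param grid_e electronic grid: a `cwf_grid`
#'   built from [electronic_submodel()]; @param Rvals numeric vector (1D
#'   nuclear block) or matrix (2D) of clamped nuclear geometries; @param
#'   nuclear_block index of the nuclear block in `model`; @param k number of
#'   surfaces; @param keep_states store electronic eigenstates; @param tol
#'   eigensolver tolerance.
#' @return object of class `bopes_table`: `Rvals`, `surfaces` (nR x k),
#'   `states` (list over R of npts_e x k matrices, phase-aligned along the
#'   scan), `grid_e`.
#' @export
compute_bopes <- function(model, grid_e, Rvals, nuclear_block, k = 1,
                          keep_states = FALSE, tol = 1e-9, align_from = NULL) {
  sub <- electronic_submodel(model, nuclear_block)
  Rmat <- if (is.matrix(Rvals)) Rvals else matrix(Rvals, ncol = 1)
  nR <- nrow(Rmat)
  H0 <- hamiltonian_sparse(sub$model, grid_e)
  Ve <- as.vector(potential_array(sub$model, grid_e))
  nE <- nrow(H0)
  surfaces <- matrix(NA_real_, nR, k)
  states <- if (keep_states) vector("list", nR) else NULL
  v0 <- NULL
  dv <- grid_dvol(grid_e)
  use_si <- grid_e$dims <= 2 && nE > 3000
  use_dense <- nE <= 700
  # processing order: scan order for 1D, outward from `align_from` for 2D
  # nuclear geometries (real eigenvectors get their sign from the nearest
  # already-aligned geometry, pushing any gauge branch cut to the far side)
  ord <- if (is.null(align_from)) seq_len(nR)
  else order(colSums((t(Rmat) - align_from)^2))
  done <- integer(0)
  for (r in ord) {
    clamp <- sub$clamped_potential(grid_e, Rmat[r, ])
    H <- H0 + Matrix::Diagonal(x = clamp$diag)
    ed <- if (use_dense) {
      dd <- eigen(as.matrix(H), symmetric = TRUE)
      idx <- order(dd$values)[seq_len(k)]
      list(values = dd$values[idx], vectors = dd$vectors[, idx, drop = FALSE])
    } else if (use_si)
      lanczos_shift_invert(H, k = k, sigma = min(Ve + clamp$diag) - 0.1, tol = tol)
    else lanczos_lowest(H, k = k, n = nE, tol = tol, v0 = v0)
    surfaces[r, ] <- ed$values + clamp$const
    v0 <- ed$vectors[, 1]
    if (keep_states) {
      ve <- ed$vectors / sqrt(dv)
      ref <- if (length(done)) {
        dists <- colSums((t(Rmat[done, , drop = FALSE]) - Rmat[r, ])^2)
        done[which.min(dists)]
      } else NA_integer_
      if (!is.na(ref)) {
        for (c in seq_len(k)) { # sign continuity toward the aligned set
          if (Re(sum(states[[ref]][, c] * ve[, c])) * dv < 0)
            ve[, c] <- -ve[, c]
        }
      }
      states[[r]] <- ve
    }
    done <- c(done, r)
  }
  structure(list(Rvals = Rmat, surfaces = surfaces, states = states,
                 grid_e = grid_e, nuclear_block = nuclear_block, k = k),
            class = "bopes_table")
}

#' @export
print.bopes_table <- function(x, ...) {
  cat(sprintf("<bopes_table> %d geometries x %d surfaces%s\n", nrow(x$Rvals),
              x$k, if (is.null(x$states)) "" else " (+ electronic states)"))
  invisible(x)
}

#' Electronic sub-model with a clamped nuclear block
#'
#' Splits a model into its electronic part (all blocks except the nuclear
#' one). The returned `clamped_potential(grid_e, R)` closure evaluates, for a
#' clamped nuclear geometry R, the electron-nuclear terms as a diagonal on the
#' electronic grid plus the nuclear-geometry constant.
#'
#' @param model a `cwf_model`; @param nuclear_block block index to clamp.
#' @export
electronic_submodel <- function(model, nuclear_block) {
  eb <- setdiff(seq_len(nrow(model$blocks)), nuclear_block)
  remap <- match(seq_len(nrow(model$blocks)), eb) # old -> new index
  pairs_e <- list(); pairs_en <- list()
  for (p in model$pairs) {
    if (p$i == nuclear_block || p$j == nuclear_block) {
      pairs_en[[length(pairs_en) + 1L]] <- p
    } else {
      pairs_e[[length(pairs_e) + 1L]] <-
        list(i = remap[p$i], j = remap[p$j], f = p$f)
    }
  }
  model_e <- model_system(model$blocks[eb, , drop = FALSE],
                          one_body = model$one_body[eb],
                          pairs = pairs_e,
                          dipole = model$dipole[eb],
                          name = paste0(model$name, "_elec"),
                          params = model$params)
  nb <- nuclear_block
  clamped_potential <- function(grid_e, R) {
    Rrow <- matrix(R, nrow = 1)
    const <- if (is.null(model$one_body[[nb]])) 0 else model$one_body[[nb]](Rrow)
    dims <- grid_e$n
    W <- array(0, dim = dims)
    for (p in pairs_en) {
      eblk <- if (p$i == nb) p$j else p$i
      Xe <- block_coords(grid_e, remap[eblk])
      Rrep <- Rrow[rep(1, nrow(Xe)), , drop = FALSE]
      vals <- if (p$i == nb) p$f(Rrep, Xe) else p$f(Xe, Rrep)
      W <- W + expand_subset_array(array(vals, dims[axes_of_block(grid_e, remap[eblk])]),
                                   axes_of_block(grid_e, remap[eblk]), dims)
    }
    list(diag = as.vector(W), const = as.numeric(const))
  }
  clamped_const <- function(R) {
    Rrow <- matrix(R, nrow = 1)
    if (is.null(model$one_body[[nb]])) 0 else as.numeric(model$one_body[[nb]](Rrow))
  }
  list(model = model_e, clamped_potential = clamped_potential,
       clamped_const = clamped_const, electron_blocks = eb, remap = remap)
}

#' One-dimensional bound-state eigensolve on a potential curve
#'
#' Finite-difference diagonalization of \eqn{-\frac{1}{2m}\partial_R^2 + v(R)}
#' (used for nuclear motion on a Born-Oppenheimer surface).
#'
#' @param axis a `cwf_axis`; @param v potential values on the axis; @param
#'   mass particle mass; @param k states; @param order FD stencil order.
#' @return list `values`, `vectors` (quadrature-normalized columns).
#' @export
curve_eigensolve <- function(axis, v, mass, k = 1, order = 4L) {
  H <- as.matrix(kinetic_matrix(axis, mass, order)) + diag(v)
  ed <- eigen(H, symmetric = TRUE)
  idx <- order(ed$values)[1:k]
  vec <- ed$vectors[, idx, drop = FALSE] / sqrt(axis$dx)
  for (c in seq_len(k)) {
    p <- which.max(abs(vec[, c]))
    if (vec[p, c] < 0) vec[, c] <- -vec[, c]
  }
  list(values = ed$values[idx], vectors = vec)
}

#' Conditional slice of a grid wavefunction
#'
#' The one-body slice \eqn{\Psi(x_i, \bar{x}_i^\alpha)} along block `i` with
#' every other coordinate clamped at the conditioning point (snapped to the
#' nearest grid nodes).
#'
#' @param wf a [grid_wavefunction()]; @param block block index to keep; @param
#'   point full configuration (one value per axis; entries for the kept block
#'   are ignored).
#' @return list of class `conditional_slice`: `raw` (unnormalized slice),
#'   `normalized`, `weight` (quadrature norm of the raw slice), `point`
#'   (snapped), `degenerate` (TRUE for an identically-zero slice).
#' @export
conditional_slice <- function(wf, block, point) {
  grid <- wf$grid
  keep <- axes_of_block(grid, block)
  idx <- vector("list", grid$dims)
  snapped <- as.numeric(point)
  for (a in seq_len(grid$dims)) {
    if (a %in% keep) idx[[a]] <- seq_len(grid$n[a])
    else {
      j <- which.min(abs(grid$axes[[a]]$x - point[a]))
      idx[[a]] <- j
      snapped[a] <- grid$axes[[a]]$x[j]
    }
  }
  raw <- do.call(`[`, c(list(wf$psi), idx, list(drop = FALSE)))
  raw <- array(raw, dim = grid$n[keep])
  dvb <- block_dvol(grid, block)
  w <- sqrt(sum(Mod(raw)^2) * dvb)
  structure(list(raw = raw, normalized = if (w > 0) raw / w else raw,
                 weight = w, point = snapped, block = block,
                 degenerate = w < 1e-300),
            class = "conditional_slice")
}

#' Kinetic correlation potential of an exact eigenstate slice
#'
#' For an eigenstate \eqn{\Psi^\gamma} and a conditioning point, evaluates the
#' complex one-body potential \eqn{\eta_i(x_i)} that collects the kinetic
#' action of all other degrees of freedom on the slice,
#' \eqn{\eta_i = (\sum_{j \ne i} K_j \Psi)/\Psi} on the slice, and verifies
#' that the slice solves its one-body eigenvalue problem with that potential.
#' Points where the slice density is below `floor` times its maximum are
#' masked (the division is singular there).
#'
#' @param model,grid model and grid; @param wf eigenstate; @param E its
#'   eigenvalue; @param block sliced block; @param point conditioning
#'   configuration; @param order FD order; @param floor density mask threshold.
#' @return list: `eta` (complex, NA at masked points), `residual` (relative
#'   residual of the one-body eigenproblem on unmasked points), `slice`.
#' @export
kinetic_correlation_potential <- function(model, grid, wf, E, block, point,
                                          order = 4L, floor = 1e-8) {
  other_axes <- setdiff(seq_len(grid$dims), axes_of_block(grid, block))
  Kpsi <- array(0, dim = grid$n)
  for (a in other_axes) {
    Ka <- kinetic_matrix(grid$axes[[a]], grid$blocks$mass[grid$axis_block[a]], order)
    Kpsi <- Kpsi + apply_axis_operator(wf$psi, Ka, a)
  }
  sl <- conditional_slice(wf, block, point)
  Ksl <- conditional_slice(grid_wavefunction(grid, Kpsi, normalize = FALSE),
                           block, point)
  dens <- Mod(sl$raw)^2
  ok <- dens >= floor * max(dens)
  eta <- array(NA_complex_, dim = dim(sl$raw))
  eta[ok] <- Ksl$raw[ok] / sl$raw[ok]
  # residual of the conditional eigenproblem on the block axes; the
  # clamped potential here is the FULL potential at the conditioning point,
  # including the terms that do not involve the sliced block (they shift the
  # conditional eigenvalue and enter the residual as constants)
  Wi <- conditional_potential_values(model, grid, block, sl$point) +
    clamped_rest_constant(model, grid, block, sl$point)
  Kb <- block_kinetic_matrix(grid, block, order)
  phi <- as.vector(sl$raw)
  lhs <- as.vector(sp_cmult(Kb, matrix(phi))) + (Wi + as.vector(eta)) * phi
  resid <- lhs - E * phi
  # FD cross-terms near masked nodes contaminate their neighbours; restrict
  # the residual to points whose full stencil is unmasked
  okmat <- array(as.vector(ok), dim = dim(sl$raw))
  half <- if (order == 4L) 2L else 1L
  core <- okmat
  dm <- dim(sl$raw)
  for (a in seq_along(dm)) {
    for (s in seq_len(half)) {
      up <- apply_axis_shift(okmat, a, s)
      dn <- apply_axis_shift(okmat, a, -s)
      core <- core & up & dn
    }
  }
  corev <- as.vector(core)
  rel <- sqrt(sum(Mod(resid[corev])^2) / max(sum(Mod(phi[corev])^2), 1e-300))
  list(eta = eta, residual = rel, slice = sl, mask = ok)
}

# logical-array shift along axis a by s (vacated entries FALSE)
apply_axis_shift <- function(m, a, s) {
  dm <- dim(m); n <- dm[a]
  out <- array(FALSE, dim = dm)
  idx_src <- idx_dst <- lapply(dm, seq_len)
  if (s > 0) { idx_src[[a]] <- seq_len(n - s); idx_dst[[a]] <- seq(s + 1, n) }
  else { idx_src[[a]] <- seq(1 - s, n); idx_dst[[a]] <- seq_len(n + s) }
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(do.call(`[`, c(list(m), idx_src, list(drop = FALSE))))))
  out
}

# sum of all model terms not involving `block`, evaluated at the clamp
clamped_rest_constant <- function(model, grid, block, point) {
  val <- 0
  for (j in seq_len(nrow(grid$blocks))) {
    if (j == block || is.null(model$one_body[[j]])) next
    val <- val + as.numeric(model$one_body[[j]](
      matrix(point[axes_of_block(grid, j)], nrow = 1)))
  }
  for (p in model$pairs) {
    if (p$i == block || p$j == block) next
    val <- val + as.numeric(p$f(
      matrix(point[axes_of_block(grid, p$i)], nrow = 1),
      matrix(point[axes_of_block(grid, p$j)], nrow = 1)))
  }
  val
}

#' Conditional one-body potential values on a block's sub-grid
#'
#' \eqn{W_i^\alpha(x_i)}: every model term involving block `i`, with all other
#' blocks clamped at the conditioning configuration (plus the one-body terms
#' of block `i` itself).
#'
#' @param model,grid model and grid; @param block block index; @param point
#'   full configuration (values for other blocks used as the clamp); @param
#'   field instantaneous field amplitude.
#' @return numeric vector over the block sub-grid (first axis fastest).
#' @export
conditional_potential_values <- function(model, grid, block, point, field = 0) {
  Xi <- block_coords(grid, block)
  v <- numeric(nrow(Xi))
  if (!is.null(model$one_body[[block]])) v <- v + model$one_body[[block]](Xi)
  for (p in model$pairs) {
    if (p$i != block && p$j != block) next
    other <- if (p$i == block) p$j else p$i
    oax <- axes_of_block(grid, other)
    Xo <- matrix(point[oax], nrow = nrow(Xi), ncol = length(oax), byrow = TRUE)
    v <- v + if (p$i == block) p$f(Xi, Xo) else p$f(Xo, Xi)
  }
  if (field != 0) {
    dd <- model$dipole[[block]]
    v <- v - field * as.vector(Xi %*% dd)
  }
  v
}
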