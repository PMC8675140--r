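#' Model system definition
#'
#' Declarative container for a grid Hamiltonian: degree-of-freedom blocks
#' (each a distinguishable particle or relative coordinate with 1 or 2 spatial
#' dimensions), per-block one-body potentials, pairwise interaction terms, and
#' length-gauge dipole couplings. All quantities are in Hartree atomic units.
#'
#' @param blocks data.frame with columns `label`, `dim` (1 or 2), `mass`
#'   (electron masses, > 0), `charge`.
#' @param one_body list (one per block) of vectorized functions `f(X)` taking
#'   an `npts x dim` coordinate matrix, or `NULL`.
#' @param pairs list of `list(i, j, f)` interaction terms, `i != j`, with
#'   `f(Xi, Xj)` vectorized over paired rows and finite on any finite grid.
#' @param dipole list (one per block) of numeric vectors (length `dim`): the
#'   coefficient of each coordinate in the dipole operator
#'   \eqn{\mu = \sum_b d_b \cdot x_b} coupling to external fields.
#' @param name model name; @param params named list of defining parameters.
#' @return object of class `cwf_model`.
#' @export
model_system <- function(blocks, one_body, pairs = list(), dipole = NULL,
                         name = "custom", params = list()) {
  stopifnot(is.data.frame(blocks),
            all(c("label", "dim", "mass", "charge") %in% names(blocks)))
  if (any(blocks$mass <= 0)) stop("masses must be positive")
  if (!all(blocks$dim %in% c(1L, 2L))) stop("blocks must be 1D or 2D")
  for (p in pairs) {
    stopifnot(is.list(p), !is.null(p$i), !is.null(p$j), is.function(p$f))
    if (p$i == p$j) stop("pair terms must reference two distinct blocks")
  }
  if (is.null(dipole)) dipole <- lapply(blocks$dim, function(d) rep(0, d))
  structure(list(blocks = blocks, one_body = one_body, pairs = pairs,
                 dipole = dipole, name = name, params = params),
            class = "cwf_model")
}

#' @export
print.cwf_model <- function(x, ...) {
  cat("<cwf_model> ", x$name, ": ", nrow(x$blocks), " blocks, ",
      length(x$pairs), " pair terms\n", sep = "")
  print(x$blocks)
  invisible(x)
}

#' Soft-Coulomb interaction
#'
#' \eqn{q/\sqrt{\epsilon + d^2}}: the Coulomb kernel with its singularity
#' removed by a smoothing parameter.
#'
#' @param d separation (any numeric array); @param eps smoothing parameter
#'   (> 0); @param q prefactor (+1 repulsive, -1 attractive).
#' @export
soft_coulomb <- function(d, eps = 1, q = 1) q / sqrt(eps + d^2)

# error function via the normal CDF (base R has no erf)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Error-function-screened Coulomb kernel
#'
#' \eqn{q\,\mathrm{erf}(d/R_c)/d}, finite at coincidence where it tends to
#' \eqn{2q/(\sqrt{\pi}R_c)}.
#' @param d separation; @param rc screening length; @param q prefactor.
#' @export
erf_coulomb <- function(d, rc, q = 1) {
  d <- abs(d)
  out <- ifelse(d < 1e-12, 2 / (sqrt(pi) * rc), erf(d / rc) / d)
  q * out
}

#' One-dimensional H2 model
#'
#' Three 1D coordinates after separating the center of mass: two electrons
#' (r1, r2) and the internuclear separation R. Reduced masses
#' \eqn{\mu_e = 2M/(2M+1)} and \eqn{\mu_n = M/2}. The electron-electron
#' repulsion and electron-nuclear attraction are soft-Coulomb with smoothing
#' \eqn{\epsilon_{ee} = 2}, \eqn{\epsilon_{en} = 1}; the nuclei repel via the
#' bare 1/R (the R grid excludes the origin). The dipole operator is
#' \eqn{\mu_e = r_1 + r_2}.
#'
#' @param M proton mass in electron masses (default 1836).
#' @param eps_ee,eps_en soft-Coulomb smoothing parameters.
#' @return a `cwf_model` with blocks r1, r2, R.
#' @export
build_h2_model <- function(M = 1836, eps_ee = 2, eps_en = 1) {
  mu_e <- 2 * M / (2 * M + 1)
  mu_n <- M / 2
  blocks <- data.frame(label = c("r1", "r2", "R"), dim = 1L,
                       mass = c(mu_e, mu_e, mu_n), charge = c(-1, -1, 1))
  en <- function(Xr, XR) {
    soft_coulomb(Xr[, 1] - XR[, 1] / 2, eps_en, -1) +
      soft_coulomb(Xr[, 1] + XR[, 1] / 2, eps_en, -1)
  }
  model_system(
    blocks,
    one_body = list(NULL, NULL, function(X) 1 / abs(X[, 1])),
    pairs = list(
      list(i = 1L, j = 2L, f = function(X1, X2) soft_coulomb(X1[, 1] - X2[, 1], eps_ee, 1)),
      list(i = 1L, j = 3L, f = en),
      list(i = 2L, j = 3L, f = en)),
    dipole = list(1, 1, 0),
    name = "h2",
    params = list(M = M, eps_ee = eps_ee, eps_en = eps_en,
                  mu_e = mu_e, mu_n = mu_n))
}

#' One-dimensional electron-hydrogen scattering model
#'
#' Two 1D electrons (mass 1) in the field of a fixed soft-Coulomb atom
#' centered at `r = 10` au, with soft electron-electron repulsion.
#'
#' @param r_atom atom position (default 10 au); @param eps soft-Coulomb
#'   smoothing for both the atomic well and the e-e repulsion.
#' @export
build_scattering_model <- function(r_atom = 10, eps = 1) {
  blocks <- data.frame(label = c("r1", "r2"), dim = 1L, mass = 1, charge = -1)
  v0 <- function(X) soft_coulomb(X[, 1] - r_atom, eps, -1)
  model_system(
    blocks,
    one_body = list(v0, v0),
    pairs = list(list(i = 1L, j = 2L,
                      f = function(X1, X2) soft_coulomb(X1[, 1] - X2[, 1], eps, 1))),
    dipole = list(1, 1),
    name = "scattering",
    params = list(r_atom = r_atom, eps = eps))
}

#' Shin-Metiu proton-coupled electron transfer model
#'
#' One electron (r) and one proton (R) moving in 1D between two fixed ions at
#' \eqn{\pm L/2}. The proton interacts with the fixed ions through the bare
#' Coulomb repulsion (divergent at the ends of the R grid, which must stay
#' inside \eqn{(-L/2, L/2)}); the electron-ion and electron-proton attractions
#' are screened by error functions with lengths `Rl` (left ion), `Rr` (right
#' ion) and `Rf` (moving proton).
#'
#' @param L fixed-ion separation (19 a0); @param Rf,Rl,Rr screening lengths
#'   (5, 4, 3.1 a0); @param M proton mass (1836).
#' @export
build_shin_metiu_model <- function(L = 19.0, Rf = 5, Rl = 4, Rr = 3.1, M = 1836) {
  blocks <- data.frame(label = c("r", "R"), dim = 1L, mass = c(1, M),
                       charge = c(-1, 1))
  model_system(
    blocks,
    one_body = list(
      # The screening lengths are attached to the fixed ions so that the
      # ground-state proton sits at R ~ -2 a0 (the weaker-screened, more
      # attractive ion binds the electron at +L/2 and the proton localizes
      # opposite to it), which fixes the otherwise arbitrary left/right
      # labelling of the printed parameter pair.
      function(X) erf_coulomb(X[, 1] - L / 2, Rl, -1) +
        erf_coulomb(X[, 1] + L / 2, Rr, -1),
      function(X) 1 / abs(L / 2 - X[, 1]) + 1 / abs(L / 2 + X[, 1])),
    pairs = list(list(i = 1L, j = 2L,
                      f = function(Xr, XR) erf_coulomb(XR[, 1] - Xr[, 1], Rf, -1))),
    dipole = list(-1, 1),
    name = "shin_metiu",
    params = list(L = L, Rf = Rf, Rl = Rl, Rr = Rr, M = M))
}

#' Two-dimensional conical-intersection model
#'
#' A quantized 2D electron and a quantized 2D proton together with two fixed
#' protons placed at \eqn{R_1 = (-0.4\sqrt{3}, 1.2)} and
#' \eqn{R_2 = (0.4\sqrt{3}, 1.2)}. With the quantized proton at the origin the
#' three protons form an equilateral (D3h) geometry, so the two lowest
#' clamped-proton electronic surfaces are degenerate there: a conical
#' intersection at the origin (any radially symmetric pair interaction gives
#' this degeneracy by symmetry). Electron-fixed-proton attraction is
#' soft-Coulomb with smoothing `a`; the electron-proton attraction is
#' erf-screened with length `R0`; the quantized proton is repelled from its
#' fixed partners by a strongly softened Coulomb term with smoothing `b`,
#' which keeps the nuclear-landscape gradients at molecular scale (heavy
#' proton momenta stay representable on desk-scale grids).
#'
#' @param a electron-ion soft-Coulomb smoothing (0.5); @param b
#'   proton-proton smoothing (10); @param R0 electron-proton screening length
#'   (1.5); @param M quantized proton mass (1836).
#' @export
build_ci_model <- function(a = 0.5, b = 10, R0 = 1.5, M = 1836) {
  R1 <- c(-0.4 * sqrt(3), 1.2)
  R2 <- c(0.4 * sqrt(3), 1.2)
  blocks <- data.frame(label = c("e", "p"), dim = 2L, mass = c(1, M),
                       charge = c(-1, 1))
  d2 <- function(X, P) (X[, 1] - P[1])^2 + (X[, 2] - P[2])^2
  model_system(
    blocks,
    one_body = list(
      function(X) -1 / sqrt(d2(X, R1) + a) - 1 / sqrt(d2(X, R2) + a),
      function(X) erf_coulomb(sqrt(d2(X, R1)), R0, 1) +
        erf_coulomb(sqrt(d2(X, R2)), R0, 1) +
        (X[, 1]^2 + X[, 2]^2) / (2 * b^2)),
    pairs = list(list(i = 1L, j = 2L,
                      f = function(Xe, Xp) {
                        -1 / sqrt((Xe[, 1] - Xp[, 1])^2 +
                                    (Xe[, 2] - Xp[, 2])^2 + a)
                      })),
    dipole = list(c(1, 0), c(0, 0)),
    name = "ci",
    params = list(a = a, b = b, R0 = R0, M = M, R1 = R1, R2 = R2))
}

#' Laser pulse in the length gauge
#'
#' \eqn{E(t) = E_0\,\Omega(t)\,\sin(\omega t)} inside the pulse window and 0
#' outside, with a \eqn{\sin^2} envelope \eqn{\Omega(t) = \sin^2(\pi t/T)}
#' vanishing at both ends. A `kick` strength can be carried for delta-kick
#' (linear response) runs; it is applied impulsively at t = 0, not through
#' `field_value()`.
#'
#' @param E0 field amplitude (a.u.); @param omega carrier frequency (a.u.);
#' @param cycles pulse duration in optical cycles (`T = cycles * 2*pi/omega`),
#'   ignored when `Tpulse` is given; @param Tpulse pulse duration (a.u.);
#' @param kick delta-kick strength kappa (a.u., << 1 for linear response).
#' @export
laser_pulse <- function(E0 = 0, omega = 0, cycles = NULL, Tpulse = NULL, kick = 0) {
  if (is.null(Tpulse)) {
    Tpulse <- if (!is.null(cycles) && omega > 0) cycles * 2 * pi / omega else 0
  }
  structure(list(E0 = E0, omega = omega, Tpulse = Tpulse, kick = kick),
            class = "laser_pulse")
}

#' Electric field value of a pulse
#' @param pulse a [laser_pulse()]; @param t time(s), >= 0 (a.u.).
#' @return field amplitude(s) in a.u.
#' @export
field_value <- function(pulse, t) {
  if (any(t < 0)) stop("negative time")
  if (is.null(pulse) || pulse$E0 == 0 || pulse$Tpulse <= 0) return(rep(0, length(t)))
  env <- ifelse(t <= pulse$Tpulse, sin(pi * t / pulse$Tpulse)^2, 0)
  pulse$E0 * env * sin(pulse$omega * t)
}

#' Full potential-energy array on a grid
#'
#' Sums every one-body and pairwise term of a model over the tensor grid
#' (plus, optionally, the length-gauge field term \eqn{-E\,\mu}).
#'
#' @param model a `cwf_model`; @param grid matching `cwf_grid`;
#' @param field instantaneous field amplitude (a.u.).
#' @return numeric array of dim `grid$n`.
#' @export
potential_array <- function(model, grid, field = 0) {
  dims <- grid$n
  W <- array(0, dim = dims)
  for (b in seq_len(nrow(model$blocks))) {
    f <- model$one_body[[b]]
    if (is.null(f)) next
    vals <- f(block_coords(grid, b))
    W <- W + expand_subset_array(array(vals, dims[axes_of_block(grid, b)]),
                                 axes_of_block(grid, b), dims)
  }
  for (p in model$pairs) {
    ai <- axes_of_block(grid, p$i); aj <- axes_of_block(grid, p$j)
    Xi <- block_coords(grid, p$i); Xj <- block_coords(grid, p$j)
    ni <- nrow(Xi); nj <- nrow(Xj)
    # all combinations, block-i index fastest
    big_i <- Xi[rep(seq_len(ni), times = nj), , drop = FALSE]
    big_j <- Xj[rep(seq_len(nj), each = ni), , drop = FALSE]
    vals <- p$f(big_i, big_j)
    sub <- c(ai, aj)
    A <- array(vals, dim = dims[sub])
    if (any(diff(sub) < 0)) { # put axes in ascending order
      o <- order(sub)
      A <- aperm(A, o); sub <- sub[o]
    }
    W <- W + expand_subset_array(A, sub, dims)
  }
  if (field != 0) W <- W - field * dipole_array(model, grid)
  W
}

#' Dipole-operator array on a grid
#' @keywords internal
dipole_array <- function(model, grid) {
  dims <- grid$n
  out <- array(0, dim = dims)
  for (b in seq_len(nrow(model$blocks))) {
    dd <- model$dipole[[b]]
    ax <- axes_of_block(grid, b)
    for (k in seq_along(ax)) {
      if (dd[k] != 0)
        out <- out + dd[k] * axis_vector_array(grid$axes[[ax[k]]]$x, ax[k], dims)
    }
  }
  out
}

# per-axis dipole coefficients as a flat vector
dipole_axis_coefs <- function(model, grid) {
  unlist(lapply(seq_len(nrow(model$blocks)), function(b) model$dipole[[b]]))
}

#' Sparse Hamiltonian matrix of a model on a grid
#'
#' Kinetic terms by finite differences (kron-sum over axes) plus the diagonal
#' potential. Hermitian (real symmetric) by construction.
#'
#' @param model a `cwf_model`; @param grid a `cwf_grid`;
#' @param field field amplitude; @param order FD stencil order.
#' @return sparse symmetric matrix of size `prod(grid$n)`.
#' @export
hamiltonian_sparse <- function(model, grid, field = 0, order = 4L) {
  dims <- grid$n; k <- length(dims)
  H <- Matrix::Diagonal(x = as.vector(potential_array(model, grid, field)))
  for (a in seq_len(k)) {
    Ka <- kinetic_matrix(grid$axes[[a]], grid$blocks$mass[grid$axis_block[a]], order)
    mats <- vector("list", k)
    for (b in seq_len(k)) mats[[b]] <- Matrix::Diagonal(dims[b])
    mats[[a]] <- Ka
    # column-major vec: first axis fastest -> kron in reverse axis order
    H <- H + Reduce(`%x%`, rev(mats))
  }
  methods::as(H, "CsparseMatrix")
}
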