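#' Uniform grid axis
#'
#' A strictly increasing, uniformly spaced coordinate axis in bohr. Axes are
#' the building blocks of tensor-product grids; each spatial dimension of each
#' degree-of-freedom block owns one axis.
#'
#' @param min,max axis end points (bohr), `min < max`.
#' @param n number of points (>= 8).
#' @return an object of class `cwf_axis` with fields `x` (points), `dx`
#'   (spacing), `n`, `min`, `max`.
#' @export
grid_axis <- function(min, max, n) {
  stopifnot(is.numeric(min), is.numeric(max), max > min)
  n <- as.integer(n)
  if (n < 8L) stop("grid axes need at least 8 points")
  x <- seq(min, max, length.out = n)
  structure(list(x = x, dx = x[2] - x[1], n = n, min = min, max = max),
            class = "cwf_axis")
}

#' Tensor-product grid for a model system
#'
#' Builds the real-space grid holding every degree-of-freedom block of a
#' model. Block `i` with spatial dimension `d` owns `d` consecutive axes.
#'
#' @param model a [model_system()].
#' @param axes a list with one entry per block; each entry is either a single
#'   `cwf_axis` (1D block) or a list of `cwf_axis` (one per component).
#' @return an object of class `cwf_grid`: `axes` (flat list of axes),
#'   `axis_block` (integer map axis -> block), `blocks` (block table from the
#'   model), `n` (points per axis), `dims` (total axis count).
#' @export
system_grid <- function(model, axes) {
  stopifnot(inherits(model, "cwf_model"), length(axes) == nrow(model$blocks))
  flat <- list(); map <- integer(0)
  for (b in seq_along(axes)) {
    ax <- axes[[b]]
    if (inherits(ax, "cwf_axis")) ax <- list(ax)
    if (length(ax) != model$blocks$dim[b])
      stop("block ", b, " needs ", model$blocks$dim[b], " axes")
    for (a in ax) {
      stopifnot(inherits(a, "cwf_axis"))
      flat <- c(flat, list(a)); map <- c(map, b)
    }
  }
  structure(list(axes = flat, axis_block = map, blocks = model$blocks,
                 n = vapply(flat, function(a) a$n, integer(1)),
                 dims = length(flat)),
            class = "cwf_grid")
}

#' @export
print.cwf_grid <- function(x, ...) {
  cat("<cwf_grid> ", x$dims, " axes, ", format(prod(as.numeric(x$n)), big.mark = ","),
      " total points\n", sep = "")
  for (a in seq_along(x$axes)) {
    ax <- x$axes[[a]]
    cat(sprintf("  axis %d (block %d, %s): [%g, %g] n=%d dx=%.4g\n", a,
                x$axis_block[a], x$blocks$label[x$axis_block[a]],
                ax$min, ax$max, ax$n, ax$dx))
  }
  invisible(x)
}

axes_of_block <- function(grid, i) which(grid$axis_block == i)

block_npts <- function(grid, i) prod(grid$n[axes_of_block(grid, i)])

#' Coordinates of one block's sub-grid
#'
#' @param grid a `cwf_grid`; @param i block index.
#' @return matrix (npts x dim) of coordinates, first axis fastest
#'   (column-major array order).
#' @keywords internal
block_coords <- function(grid, i) {
  ax <- axes_of_block(grid, i)
  xs <- lapply(grid$axes[ax], function(a) a$x)
  if (length(xs) == 1L) return(matrix(xs[[1]], ncol = 1))
  as.matrix(expand.grid(xs, KEEP.OUT.ATTRS = FALSE))
}

#' Volume element of a block's sub-grid
#' @keywords internal
block_dvol <- function(grid, i) prod(vapply(grid$axes[axes_of_block(grid, i)],
                                            function(a) a$dx, numeric(1)))

#' Volume element of the full tensor grid
#' @param grid a `cwf_grid`.
#' @export
grid_dvol <- function(grid) prod(vapply(grid$axes, function(a) a$dx, numeric(1)))

#' Finite-difference second-derivative matrix on one axis
#'
#' Central stencils with implicit zero (Dirichlet) boundaries.
#'
#' @param axis a `cwf_axis`; @param order stencil order, 2 or 4.
#' @return sparse symmetric `n x n` matrix approximating d2/dx2.
#' @keywords internal
second_derivative_matrix <- function(axis, order = 4L) {
  n <- axis$n; h2 <- axis$dx^2
  if (order == 2L) {
    Matrix::bandSparse(n, k = c(-1, 0, 1),
                       diagonals = list(rep(1, n - 1), rep(-2, n), rep(1, n - 1)),
                       symmetric = FALSE) / h2
  } else if (order == 4L) {
    Matrix::bandSparse(n, k = -2:2,
                       diagonals = list(rep(-1 / 12, n - 2), rep(4 / 3, n - 1),
                                        rep(-5 / 2, n), rep(4 / 3, n - 1),
                                        rep(-1 / 12, n - 2)),
                       symmetric = FALSE) / h2
  } else stop("stencil order must be 2 or 4")
}

#' Kinetic-energy operator matrix on one axis
#'
#' \eqn{-\frac{1}{2m}\partial_x^2} by central finite differences.
#'
#' @param axis a `cwf_axis`; @param mass particle mass (a.u., > 0);
#' @param order stencil order (2 or 4, default 4).
#' @return sparse symmetric matrix.
#' @export
kinetic_matrix <- function(axis, mass, order = 4L) {
  if (!is.numeric(mass) || mass <= 0) stop("mass must be positive")
  if (axis$n < 5L) stop("kinetic stencil needs at least 5 points")
  -second_derivative_matrix(axis, order) / (2 * mass)
}

#' Apply the kinetic operator to amplitudes on one axis
#'
#' @param psi complex (or real) amplitude vector on the axis.
#' @param mass particle mass; @param axis a `cwf_axis`; @param order stencil order.
#' @return amplitudes of \eqn{-\frac{1}{2m}\psi''}.
#' @export
apply_kinetic <- function(psi, mass, axis, order = 4L) {
  stopifnot(length(psi) == axis$n)
  as.vector(kinetic_matrix(axis, mass, order) %*% psi)
}

#' Kinetic operator for a whole (possibly 2D) block
#' @keywords internal
block_kinetic_matrix <- function(grid, i, order = 4L) {
  ax <- axes_of_block(grid, i)
  m <- grid$blocks$mass[i]
  mats <- lapply(grid$axes[ax], kinetic_matrix, mass = m, order = order)
  if (length(mats) == 1L) return(mats[[1]])
  # column-major vec: first axis fastest => K = I2 %x% K1 + K2 %x% I1
  n1 <- grid$n[ax[1]]; n2 <- grid$n[ax[2]]
  Matrix::Diagonal(n2) %x% mats[[1]] + mats[[2]] %x% Matrix::Diagonal(n1)
}

#' Local cubic (4-point Lagrange) interpolation with derivative
#'
#' Evaluates amplitudes and their first derivative off-grid. Exact at grid
#' nodes and for polynomials up to degree 3.
#'
#' @param axis a `cwf_axis`.
#' @param psi amplitude vector, or a matrix whose columns are interpolated
#'   simultaneously.
#' @param xq query points (inside the axis range).
#' @return list with `value` and `deriv`; vectors for vector input, matrices
#'   (length(xq) x ncol) for matrix input.
#' @export
interp_cubic <- function(axis, psi, xq) {
  x0 <- axis$min; dx <- axis$dx; n <- axis$n
  if (any(xq < axis$min - 1e-9) || any(xq > axis$max + 1e-9))
    stop("interpolation query outside grid bounds")
  mat <- is.matrix(psi)
  P <- if (mat) psi else matrix(psi, ncol = 1)
  tt <- (xq - x0) / dx
  i0 <- floor(tt)
  i0 <- pmin(pmax(i0, 1L), n - 3L)        # stencil i0-? : clamp to [1, n-3]
  s <- tt - i0                             # local coordinate in [.,.] wrt node i0
  # nodes i0-1, i0, i0+1, i0+2 (0-based) -> R indices i0, i0+1, i0+2, i0+3
  # Lagrange weights for points at s = -1, 0, 1, 2
  w0 <- -s * (s - 1) * (s - 2) / 6
  w1 <- (s + 1) * (s - 1) * (s - 2) / 2
  w2 <- -(s + 1) * s * (s - 2) / 2
  w3 <- (s + 1) * s * (s - 1) / 6
  d0 <- (-3 * s^2 + 6 * s - 2) / 6
  d1 <- (3 * s^2 - 4 * s - 1) / 2
  d2 <- (-3 * s^2 + 2 * s + 2) / 2
  d3 <- (3 * s^2 - 1) / 6
  val <- w0 * P[i0, , drop = FALSE] + w1 * P[i0 + 1L, , drop = FALSE] +
    w2 * P[i0 + 2L, , drop = FALSE] + w3 * P[i0 + 3L, , drop = FALSE]
  der <- (d0 * P[i0, , drop = FALSE] + d1 * P[i0 + 1L, , drop = FALSE] +
            d2 * P[i0 + 2L, , drop = FALSE] + d3 * P[i0 + 3L, , drop = FALSE]) / dx
  if (mat) list(value = val, deriv = der)
  else list(value = as.vector(val), deriv = as.vector(der))
}

#' Smooth absorbing mask on one axis
#'
#' Equals 1 in the interior and decreases monotonically to a minimum < 1 at
#' the edges over a fraction `frac` of the axis on each side, using a
#' \eqn{\cos^{1/8}} profile. Applied multiplicatively each time step to soak
#' up outgoing (ionized/scattered) amplitude.
#'
#' @param axis a `cwf_axis`; @param frac edge width as a fraction of the axis
#'   length, in (0, 0.5).
#' @return numeric vector of per-point damping factors in (0, 1].
#' @export
absorbing_mask <- function(axis, frac = 0.1) {
  if (!is.numeric(frac) || frac <= 0 || frac >= 0.5)
    stop("mask width fraction must be in (0, 0.5)")
  L <- axis$max - axis$min; w <- frac * L
  m <- rep(1, axis$n)
  dl <- axis$x - axis$min
  dr <- axis$max - axis$x
  left <- dl < w; right <- dr < w
  m[left] <- abs(cos(pi / 2 * (w - dl[left]) / w))^(1 / 8)
  m[right] <- abs(cos(pi / 2 * (w - dr[right]) / w))^(1 / 8)
  # never exactly zero at the last point to keep propagation well-defined
  pmax(m, 1e-8)
}

#' Full-grid absorbing mask array
#' @param grid a `cwf_grid`; @param frac per-axis width fraction (recycled).
#' @return array of dim `grid$n` (product of per-axis masks).
#' @export
grid_mask <- function(grid, frac = 0.1) {
  frac <- rep(frac, length.out = grid$dims)
  masks <- Map(absorbing_mask, grid$axes, frac)
  expand_axes_product(masks, grid$n)
}

# product of per-axis vectors expanded to a full array
expand_axes_product <- function(vecs, dims) {
  out <- array(1, dim = dims)
  for (a in seq_along(vecs)) {
    out <- out * axis_vector_array(vecs[[a]], a, dims)
  }
  out
}

# replicate a per-axis vector into a full array along axis a
axis_vector_array <- function(v, a, dims) {
  k <- length(dims)
  before <- if (a > 1) prod(dims[seq_len(a - 1)]) else 1
  after <- if (a < k) prod(dims[seq(a + 1, k)]) else 1
  array(rep(rep(v, each = before), times = after), dim = dims)
}

# expand an array defined on a subset of axes (ascending order) to the full grid
expand_subset_array <- function(A, subset, dims) {
  k <- length(dims)
  rest <- setdiff(seq_len(k), subset)
  if (length(rest) == 0L) return(array(A, dim = dims))
  B <- array(rep(as.vector(A), times = prod(dims[rest])),
             dim = c(dims[subset], dims[rest]))
  aperm(B, order(c(subset, rest)))
}

#' Grid wavefunction
#'
#' Complex amplitudes on the full tensor grid, normalized so that the Riemann
#' quadrature of \eqn{|\Psi|^2} is 1.
#'
#' @param grid a `cwf_grid`; @param psi complex array of dim `grid$n`;
#' @param time time stamp (a.u.); @param normalize renormalize on construction.
#' @return object of class `grid_wavefunction`.
#' @export
grid_wavefunction <- function(grid, psi, time = 0, normalize = TRUE) {
  psi <- array(as.complex(psi), dim = grid$n)
  if (any(!is.finite(Re(psi))) || any(!is.finite(Im(psi))))
    stop("non-finite amplitudes")
  if (normalize) {
    nrm <- sqrt(sum(Mod(psi)^2) * grid_dvol(grid))
    if (nrm == 0) stop("cannot normalize a zero wavefunction")
    psi <- psi / nrm
  }
  structure(list(grid = grid, psi = psi, time = time), class = "grid_wavefunction")
}

#' @export
print.grid_wavefunction <- function(x, ...) {
  cat(sprintf("<grid_wavefunction> %s points, t = %.4g au, norm = %.8f\n",
              format(prod(as.numeric(x$grid$n)), big.mark = ","), x$time, wf_norm(x)))
  invisible(x)
}

#' Quadrature norm of a grid wavefunction
#' @param wf a `grid_wavefunction`.
#' @return \eqn{\sqrt{\int |\Psi|^2 dx}}.
#' @export
wf_norm <- function(wf) sqrt(sum(Mod(wf$psi)^2) * grid_dvol(wf$grid))

#' Quadrature inner product of two grid wavefunctions
#' @keywords internal
wf_dot <- function(a, b) sum(Conj(a$psi) * b$psi) * grid_dvol(a$grid)
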