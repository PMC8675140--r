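#' Stochastic conditioning-configuration ensembles
#'
#' The ICWF ansatz is anchored at `N_c` conditioning configurations
#' \eqn{x^\alpha} drawn from (a guess for) the system's probability density.
#' This module provides seeded, bitwise-reproducible sampling from grid
#' densities, either from the product of per-axis marginals (`"marginals"`,
#' the default guess mode) or from the full joint density (`"joint"`).
#'
#' Draws are cell-exact: a grid cell is selected with probability
#' proportional to its density and the position is jittered uniformly within
#' the cell, which samples the piecewise-constant density exactly.
#'
#' @param density a [grid_wavefunction()] (its \eqn{|\Psi|^2} is used), a
#'   non-negative array on `grid`, or a list of per-axis non-negative
#'   marginal vectors.
#' @param grid the `cwf_grid` the density lives on.
#' @param n_configs number of configurations `N_c` (>= 1).
#' @param seed integer seed; same (seed, inputs) gives identical ensembles.
#' @param mode `"marginals"` (sample each axis from its marginal) or
#'   `"joint"` (sample full grid cells).
#' @return object of class `configuration_ensemble`: `configs`
#'   (`n_configs x dims` matrix), `seed`, `mode`, `grid`.
#' @export
sample_configurations <- function(density, grid, n_configs, seed = 1L,
                                  mode = c("marginals", "joint")) {
  mode <- match.arg(mode)
  n_configs <- as.integer(n_configs)
  if (n_configs < 1L) stop("need at least one configuration")
  dens <- density_as_array(density, grid)
  if (is.list(dens$marginals) && mode == "joint" && is.null(dens$joint))
    stop("joint sampling needs a full grid density")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  X <- matrix(NA_real_, n_configs, grid$dims)
  if (mode == "joint") {
    p <- as.vector(dens$joint)
    tot <- sum(p)
    if (tot <= 0) stop("zero density")
    cells <- sample.int(length(p), n_configs, replace = TRUE, prob = p / tot)
    idx <- arrayInd(cells, grid$n)
    for (a in seq_len(grid$dims)) {
      ax <- grid$axes[[a]]
      X[, a] <- ax$x[idx[, a]] + (stats::runif(n_configs) - 0.5) * ax$dx
      X[, a] <- pmin(pmax(X[, a], ax$min), ax$max)
    }
  } else {
    for (a in seq_len(grid$dims)) {
      ax <- grid$axes[[a]]
      p <- dens$marginals[[a]]
      tot <- sum(p)
      if (tot <= 0) stop("zero density on axis ", a)
      if (n_configs > 4 * sum(p > max(p) * 1e-6))
        warning("N_c exceeds the distinct support of axis ", a)
      cells <- sample.int(ax$n, n_configs, replace = TRUE, prob = p / tot)
      X[, a] <- ax$x[cells] + (stats::runif(n_configs) - 0.5) * ax$dx
      X[, a] <- pmin(pmax(X[, a], ax$min), ax$max)
    }
  }
  structure(list(configs = X, seed = seed, mode = mode, grid = grid),
            class = "configuration_ensemble")
}

#' @export
print.configuration_ensemble <- function(x, ...) {
  cat(sprintf("<configuration_ensemble> %d configs x %d axes (seed %d, %s)\n",
              nrow(x$configs), ncol(x$configs), x$seed, x$mode))
  invisible(x)
}

# normalize the accepted density inputs
density_as_array <- function(density, grid) {
  if (inherits(density, "grid_wavefunction")) {
    joint <- Mod(density$psi)^2
    return(list(joint = joint, marginals = joint_marginals(joint, grid)))
  }
  if (is.list(density) && !is.data.frame(density)) {
    stopifnot(length(density) == grid$dims)
    for (a in seq_len(grid$dims)) {
      if (length(density[[a]]) != grid$n[a]) stop("marginal length mismatch")
      if (any(density[[a]] < -1e-12)) stop("density must be non-negative")
    }
    return(list(joint = NULL, marginals = lapply(density, pmax, 0)))
  }
  arr <- array(density, dim = grid$n)
  if (any(arr < -1e-12)) stop("density must be non-negative")
  arr <- pmax(arr, 0)
  list(joint = arr, marginals = joint_marginals(arr, grid))
}

joint_marginals <- function(arr, grid) {
  lapply(seq_len(grid$dims), function(a)
    as.vector(apply(arr, a, sum)))
}

#' Close an ensemble under identical-particle exchange
#'
#' For a pair of identical blocks, appends to the ensemble the label-swapped
#' twin of every configuration that is not already present (so a
#' spatially symmetric state is sampled symmetrically). At most doubles
#' `N_c`.
#'
#' @param ens a `configuration_ensemble`; @param blocks integer pair of
#'   identical block indices (default: first two blocks with equal mass,
#'   dimension and charge).
#' @param tol coordinate tolerance for the already-present check.
#' @export
symmetrize_ensemble <- function(ens, blocks = NULL, tol = 1e-12) {
  grid <- ens$grid
  if (is.null(blocks)) {
    bt <- grid$blocks
    cand <- which(duplicated(bt[, c("dim", "mass", "charge")]) |
                    duplicated(bt[, c("dim", "mass", "charge")], fromLast = TRUE))
    if (length(cand) < 2) stop("no identical-particle blocks found")
    blocks <- cand[1:2]
  }
  a1 <- axes_of_block(grid, blocks[1]); a2 <- axes_of_block(grid, blocks[2])
  stopifnot(length(a1) == length(a2))
  X <- ens$configs
  Xs <- X
  Xs[, a1] <- X[, a2]; Xs[, a2] <- X[, a1]
  have <- apply(X, 1, paste, collapse = "\r")
  add <- Xs[!(apply(Xs, 1, paste, collapse = "\r") %in% have), , drop = FALSE]
  out <- ens
  out$configs <- rbind(X, add)
  out
}
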