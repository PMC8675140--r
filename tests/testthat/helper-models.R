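# Small fixture builders shared across the suite (everything generated in
# code; no stored data).

# 1D harmonic oscillator, unit mass and frequency
ho_model <- function(omega = 1, mass = 1) {
  model_system(data.frame(label = "x", dim = 1L, mass = mass, charge = 0),
               one_body = list(function(X) 0.5 * mass * omega^2 * X[, 1]^2),
               dipole = list(1), name = "ho",
               params = list(omega = omega))
}

free_model <- function(mass = 1) {
  model_system(data.frame(label = "x", dim = 1L, mass = mass, charge = 0),
               one_body = list(function(X) 0 * X[, 1]), name = "free")
}

# two coupled distinguishable 1D particles (generic correlated toy)
toy2_model <- function(coupling = 0.8) {
  model_system(
    data.frame(label = c("a", "b"), dim = 1L, mass = c(1, 2), charge = 0),
    one_body = list(function(X) 0.5 * X[, 1]^2, function(X) X[, 1]^2),
    pairs = list(list(i = 1L, j = 2L,
                      f = function(X1, X2) coupling / sqrt(1 + (X1[, 1] - X2[, 1])^2))),
    dipole = list(1, 1), name = "toy2")
}

toy2_grid <- function(model, n = 16L) {
  system_grid(model, list(grid_axis(-6, 6, n), grid_axis(-5, 5, n)))
}

# separable two-particle model (no pair term)
sep_model <- function() {
  model_system(
    data.frame(label = c("a", "b"), dim = 1L, mass = c(1, 1.5), charge = 0),
    one_body = list(function(X) 0.5 * X[, 1]^2, function(X) 0.3 * X[, 1]^2),
    dipole = list(1, 0), name = "sep")
}

# small scaled-down H2 grids used by several tests
h2_small_grid <- function(model, n_r = 32L, n_R = 24L, r_ext = 14) {
  system_grid(model, list(grid_axis(-r_ext, r_ext, n_r),
                          grid_axis(-r_ext, r_ext, n_r),
                          grid_axis(0.3, 4.5, n_R)))
}
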