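# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# 10^3 lattice, near-spherical mask: N = 360 voxels, P = 27 bases at 8mm
small_grid <- function() {
  if (is.null(.fix$g_small))
    .fix$g_small <- synthetic_ellipsoid_grid(dims = c(10, 10, 10),
                                             voxel_mm = 2,
                                             semiaxes_mm = c(9, 9, 9))
  .fix$g_small
}

small_basis <- function() {
  if (is.null(.fix$b_small))
    .fix$b_small <- build_basis(small_grid(), knot_config(8))
  .fix$b_small
}

# the default toy study space used by the calibration experiments
toy_grid <- function() {
  if (is.null(.fix$g_toy)) .fix$g_toy <- synthetic_ellipsoid_grid()
  .fix$g_toy
}

toy_basis <- function() {
  if (is.null(.fix$b_toy)) .fix$b_toy <- build_basis(toy_grid(), knot_config(12))
  .fix$b_toy
}

# wrap an arbitrary row matrix as a spline_basis for model-level tests
dummy_basis <- function(X) {
  structure(list(X = methods::as(Matrix::Matrix(X, sparse = TRUE),
                                 "CsparseMatrix"),
                 P = ncol(X), kept_columns = seq_len(ncol(X)),
                 per_axis_counts = c(ncol(X), 1L, 1L),
                 config = knot_config(1), support_threshold = 0),
            class = "spline_basis")
}

# random small dense instance for factorization-fidelity checks
random_instance <- function(N, M, P, R, seed) {
  set.seed(seed)
  X <- matrix(runif(N * P, 0.05, 1), N, P)
  X <- X / rowSums(X)
  Z <- if (R > 0) scale(matrix(rnorm(M * R), M, R), scale = FALSE) else NULL
  beta <- rnorm(P, -0.5, 0.5)
  gamma <- if (R > 0) rnorm(R, 0, 0.3) else numeric(0)
  Y <- matrix(rbinom(M * N, 1, 0.3), M, N)
  data <- list(M = M, N = N, y_voxel = colSums(Y), y_study = rowSums(Y),
               total_foci = sum(Y))
  list(X = X, Z = Z, beta = beta, gamma = gamma, Y = Y, data = data,
       basis = dummy_basis(X))
}

# minimal cbmr_data from explicit sufficient statistics
stub_data <- function(y_voxel, y_study, grid = NULL) {
  structure(list(M = length(y_study), N = length(y_voxel),
                 y_voxel = as.numeric(y_voxel),
                 y_study = as.numeric(y_study),
                 total_foci = sum(y_voxel), incidence = NULL, grid = grid,
                 report = list()),
            class = "cbmr_data")
}

# write a foci table for I/O tests
write_foci_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
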