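#' Knot configuration for the tensor-product B-spline basis
#'
#' Knots are equally spaced along each axis in mm. The knot lattice is
#' anchored at the mm origin (a knot sits at every integer multiple of the
#' spacing), covers the axis extent, and is extended past both ends by
#' `degree` additional equally spaced knots, so the basis is uniform (not
#' clamped) and every voxel centre lies in the interior where B-splines
#' partition unity.
#'
#' @param spacing_mm knot spacing in mm; scalar or length-3 (x, y, z).
#' @param degree spline degree (3 = cubic).
#' @return list of class `knot_config`.
#' @export
knot_config <- function(spacing_mm = 20, degree = 3L) {
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("knot spacing must be positive")
  structure(list(spacing_mm = spacing_mm, degree = as.integer(degree)),
            class = "knot_config")
}

axis_knots <- function(coords_mm, spacing, degree) {
  kmin <- spacing * floor(min(coords_mm) / spacing)
  kmax <- spacing * ceiling(max(coords_mm) / spacing)
  if ((kmax - kmin) < spacing)
    kmax <- kmin + spacing
  seq(kmin - degree * spacing, kmax + degree * spacing, by = spacing)
}

#' Evaluate a 1D equally spaced B-spline basis at voxel centres
#'
#' @param coords_mm mm coordinates of the voxel centres along one axis
#'   (need not be increasing).
#' @param spacing knot spacing in mm.
#' @param degree spline degree (3 = cubic; 0 gives the piecewise-constant
#'   histogram basis).
#' @return list with `B` (length(coords) x n coefficient matrix) and `knots`.
#'   Rows of `B` sum to 1 (partition of unity on the interior, which with the
#'   extended uniform knot vector is the whole axis).
#' @export
bspline_axis <- function(coords_mm, spacing, degree = 3L) {
  degree <- as.integer(degree)
  ext <- diff(range(coords_mm))
  if (length(coords_mm) > 1 && spacing > ext + max(abs(diff(coords_mm))))
    stop("degenerate-basis error: knot spacing exceeds axis extent")
  knots <- axis_knots(coords_mm, spacing, degree)
  B <- splines::splineDesign(knots, coords_mm, ord = degree + 1L,
                             outer.ok = FALSE)
  list(B = B, knots = knots)
}

#' Dense tensor product of per-axis coefficient matrices
#'
#' Explicit small-scale construction of the full-volume coefficient matrix
#' `C`: the entry for voxel (i, j, k) and basis (a, b, c) is
#' `Cx[i,a] * Cy[j,b] * Cz[k,c]`. Rows are ordered with the x lattice index
#' fastest (R column-major array order, matching [masked_grid] linear
#' ordering); columns with the x basis index fastest. Intended for small
#' grids and oracle checks; production grids use the sparse in-mask assembly
#' of [build_basis], which never materializes `C`.
#'
#' @param Cx,Cy,Cz per-axis coefficient matrices (v_x x n_x etc.).
#' @return (v_x v_y v_z) x (n_x n_y n_z) matrix.
#' @export
tensor_basis <- function(Cx, Cy, Cz) {
  Cx <- as.matrix(Cx); Cy <- as.matrix(Cy); Cz <- as.matrix(Cz)
  kronecker(Cz, kronecker(Cy, Cx))
}

#' Mask, prune, and renormalize a full-lattice coefficient matrix
#'
#' The three-step reduction from the full tensor basis to the design matrix:
#' (1) drop rows of voxels outside the mask; (2) drop weakly supported
#' columns, i.e. bases whose maximum coefficient over in-mask voxels is
#' strictly below `support_threshold`; (3) rescale each remaining row to sum
#' to one, restoring the partition of unity on the retained basis.
#'
#' @param C full-lattice coefficient matrix (rows ordered as in
#'   [tensor_basis], x index fastest).
#' @param grid a [masked_grid] with `prod(dims)` equal to `nrow(C)`.
#' @param support_threshold pruning threshold on the in-mask column maximum
#'   (default 0.1).
#' @return list with `X` (N x P design matrix), `P`, `kept_columns`.
#' @export
mask_prune_renormalize <- function(C, grid, support_threshold = 0.1) {
  if (nrow(C) != prod(grid$dims))
    stop("geometry error: C rows do not match the grid lattice")
  Xm <- C[as.vector(grid$mask), , drop = FALSE]
  colmax <- apply(Xm, 2, max)
  keep <- which(colmax >= support_threshold)
  if (support_threshold <= 0) keep <- which(colmax > 0)
  Xm <- Xm[, keep, drop = FALSE]
  rs <- rowSums(Xm)
  bad <- which(rs <= 0)
  if (length(bad) > 0)
    stop("basis-coverage error: voxel ", bad[1],
         " has no support after pruning")
  list(X = Xm / rs, P = length(keep), kept_columns = keep)
}

#' Build the pruned, renormalized tensor-product B-spline design matrix
#'
#' Assembles the N x P spatial design matrix directly on the in-mask voxels,
#' exploiting the fact that a degree-d tensor B-spline has at most (d+1)^3
#' nonzero bases at any voxel: the full-lattice coefficient matrix is never
#' materialized. Columns are then pruned (in-mask maximum strictly below
#' `support_threshold`) and rows renormalized to sum to one.
#'
#' @param grid a [masked_grid].
#' @param config a [knot_config] (or spacing in mm, taken as
#'   `knot_config(spacing)`).
#' @param support_threshold pruning threshold, default 0.1.
#' @return object of class `spline_basis`: `X` (sparse N x P,
#'   `Matrix::dgCMatrix`), `P`, `kept_columns` (indices into the full tensor
#'   basis, x basis index fastest), `per_axis_counts`, `knots` (per-axis
#'   list), `config`, `support_threshold`.
#' @export
build_basis <- function(grid, config = knot_config(), support_threshold = 0.1) {
  if (is.numeric(config)) config <- knot_config(config)
  stopifnot(inherits(config, "knot_config"))
  d <- config$degree
  ax <- lapply(1:3, function(a)
    bspline_axis(axis_mm(grid, a), config$spacing_mm[a], d))
  nb <- vapply(ax, function(b) ncol(b$B), integer(1))
  # compact per-axis representation: first nonzero column + (d+1) values
  compact <- lapply(ax, function(b) {
    nz <- b$B != 0
    first <- max.col(nz, ties.method = "first")
    # clamp so a full (d+1)-window fits (edge rows can have fewer nonzeros)
    first <- pmin(first, ncol(b$B) - d)
    vals <- matrix(0, nrow(b$B), d + 1L)
    for (r in 0:d) vals[, r + 1L] <- b$B[cbind(seq_len(nrow(b$B)), first + r)]
    list(first = first, vals = vals)
  })
  pos <- grid$voxel_lattice + 1L  # 1-based lattice indices
  N <- grid$n_voxels
  fx <- compact[[1]]$first[pos[, 1]]; vx <- compact[[1]]$vals[pos[, 1], , drop = FALSE]
  fy <- compact[[2]]$first[pos[, 2]]; vy <- compact[[2]]$vals[pos[, 2], , drop = FALSE]
  fz <- compact[[3]]$first[pos[, 3]]; vz <- compact[[3]]$vals[pos[, 3], , drop = FALSE]
  nsup <- (d + 1L)^3
  ii <- rep(seq_len(N), nsup)
  jj <- integer(N * nsup)
  xx <- numeric(N * nsup)
  s <- 0L
  for (c in 0:d) for (b in 0:d) for (a in 0:d) {
    rng <- (s * N + 1L):((s + 1L) * N)
    jj[rng] <- (fx + a) + nb[1] * ((fy + b - 1L) + nb[2] * (fz + c - 1L))
    xx[rng] <- vx[, a + 1L] * vy[, b + 1L] * vz[, c + 1L]
    s <- s + 1L
  }
  nzsel <- xx != 0
  C <- Matrix::sparseMatrix(i = ii[nzsel], j = jj[nzsel], x = xx[nzsel],
                            dims = c(N, prod(nb)))
  # column maxima without densifying: use the sparse slot structure
  Ccsc <- methods::as(C, "CsparseMatrix")
  cm <- numeric(ncol(C))
  np <- diff(Ccsc@p)
  if (length(Ccsc@x) > 0) {
    grp <- rep.int(seq_len(ncol(C)), np)
    cm[unique(grp)] <- tapply(Ccsc@x, grp, max)
  }
  keep <- if (support_threshold <= 0) which(cm > 0) else which(cm >= support_threshold)
  X <- C[, keep, drop = FALSE]
  rs <- Matrix::rowSums(X)
  bad <- which(rs <= 0)
  if (length(bad) > 0)
    stop("basis-coverage error: voxel ", bad[1],
         " has no supporting basis after pruning; reduce knot spacing or ",
         "the support threshold")
  X <- Matrix::Diagonal(x = 1 / rs) %*% X
  structure(
    list(X = methods::as(X, "CsparseMatrix"), P = length(keep),
         kept_columns = keep, per_axis_counts = nb,
         knots = lapply(ax, `[[`, "knots"), config = config,
         support_threshold = support_threshold),
    class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("spline_basis: P =", x$P, "of", prod(x$per_axis_counts),
      "tensor bases retained (per-axis",
      paste(x$per_axis_counts, collapse = " x "), ")\n")
  invisible(x)
}

#' Export a basis summary as JSON
#'
#' @param basis a `spline_basis`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
basis_summary_json <- function(basis, path = NULL) {
  s <- list(P = basis$P, per_axis_counts = basis$per_axis_counts,
            kept_columns = basis$kept_columns,
            spacing_mm = basis$config$spacing_mm,
            degree = basis$config$degree,
            support_threshold = basis$support_threshold)
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
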