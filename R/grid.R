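#' Masked voxel grid
#'
#' A `masked_grid` holds a regular 3D voxel lattice, a 4x4 affine mapping
#' 0-based voxel indices to millimetre coordinates, and a boolean brain mask.
#' It defines the discrete sampling space of a coordinate-based
#' meta-regression: the `N` in-mask voxels and the bijection between lattice
#' positions and linear indices `1..N`.
#'
#' The in-mask linear ordering follows R's column-major array order (x index
#' fastest, then y, then z), i.e. the order of `which(mask)`.
#'
#' @param mask logical 3D array; `TRUE` marks in-mask voxels.
#' @param affine 4x4 numeric matrix mapping homogeneous 0-based voxel indices
#'   `(i, j, k, 1)` to mm coordinates, NIfTI convention.
#' @return An object of class `masked_grid` with elements `dims`, `affine`,
#'   `mask`, `n_voxels`, `voxel_lattice` (N x 3 integer matrix of 0-based
#'   in-mask positions) and `index_lookup` (integer array over the lattice,
#'   `NA` outside the mask).
#' @export
masked_grid <- function(mask, affine) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("`mask` contains NA")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !all(is.finite(affine)))
    stop("`affine` must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("geometry error: affine is singular")
  dims <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  pos <- arrayInd(idx, dims) - 1L  # 0-based lattice positions
  lookup <- array(NA_integer_, dim = dims)
  lookup[idx] <- seq_along(idx)
  structure(
    list(dims = dims, affine = affine, mask = mask,
         n_voxels = length(idx), voxel_lattice = pos,
         index_lookup = lookup),
    class = "masked_grid")
}

#' @export
print.masked_grid <- function(x, ...) {
  cat("masked_grid: ", paste(x$dims, collapse = " x "),
      " lattice, N = ", x$n_voxels, " in-mask voxels\n", sep = "")
  invisible(x)
}

#' Standard 2mm MNI affine
#'
#' The affine of the 91 x 109 x 91 2mm MNI template: voxel steps
#' (-2, 2, 2) mm with mm origin at voxel (45, 63, 36).
#' @return 4x4 numeric matrix.
#' @export
mni152_affine_2mm <- function() {
  rbind(c(-2, 0, 0, 90),
        c(0, 2, 0, -126),
        c(0, 0, 2, -72),
        c(0, 0, 0, 1))
}

#' Convert lattice positions to linear in-mask indices and back
#'
#' @param grid a [masked_grid].
#' @param pos n x 3 integer matrix of 0-based lattice positions.
#' @return `voxel_to_index`: integer vector of 1..N indices (`NA` for
#'   out-of-mask positions). `index_to_voxel`: n x 3 matrix of 0-based
#'   positions.
#' @export
voxel_to_index <- function(grid, pos) {
  pos <- matrix(as.integer(pos), ncol = 3L)
  ok <- pos[, 1] >= 0L & pos[, 1] < grid$dims[1] &
        pos[, 2] >= 0L & pos[, 2] < grid$dims[2] &
        pos[, 3] >= 0L & pos[, 3] < grid$dims[3]
  out <- rep(NA_integer_, nrow(pos))
  if (any(ok)) {
    lin <- pos[ok, 1] + grid$dims[1] * (pos[ok, 2] + grid$dims[2] * pos[ok, 3]) + 1
    out[ok] <- grid$index_lookup[lin]
  }
  out
}

#' @rdname voxel_to_index
#' @param index integer vector of in-mask linear indices (1..N).
#' @export
index_to_voxel <- function(grid, index) {
  grid$voxel_lattice[index, , drop = FALSE]
}

# round half away from zero; base round() rounds half to even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map mm coordinates to voxel lattice positions
#'
#' Applies the inverse affine and rounds to the nearest lattice position
#' (ties rounded half away from zero). Positions outside the lattice are
#' flagged, never silently dropped.
#'
#' @param xyz n x 3 numeric matrix of mm coordinates.
#' @param grid a [masked_grid].
#' @return list with `pos` (n x 3 integer, 0-based; rows may lie outside the
#'   lattice), `in_lattice` (logical) and `in_mask` (logical).
#' @export
mm_to_voxel <- function(xyz, grid) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  if (!all(is.finite(xyz))) stop("non-finite mm coordinates")
  inv <- solve(grid$affine)
  hom <- cbind(xyz, 1) %*% t(inv)
  pos <- round_half_away(hom[, 1:3, drop = FALSE])
  storage.mode(pos) <- "integer"
  in_lattice <- pos[, 1] >= 0L & pos[, 1] < grid$dims[1] &
                pos[, 2] >= 0L & pos[, 2] < grid$dims[2] &
                pos[, 3] >= 0L & pos[, 3] < grid$dims[3]
  idx <- voxel_to_index(grid, pos)
  list(pos = pos, in_lattice = in_lattice, in_mask = !is.na(idx), index = idx)
}

#' mm coordinates of voxel centers along one axis
#'
#' Coordinates of lattice positions `0..dims[axis]-1` along `axis`, holding
#' the other two indices at zero, projected on that axis. Valid for
#' axis-aligned (diagonal) affines, which is the case for NIfTI-convention
#' masks used here.
#' @keywords internal
axis_mm <- function(grid, axis) {
  n <- grid$dims[axis]
  grid$affine[axis, axis] * (0:(n - 1)) + grid$affine[axis, 4]
}

#' Read a NIfTI mask into a masked grid
#'
#' @param path path to a NIfTI volume; voxels with value > `threshold` form
#'   the mask.
#' @param threshold inclusion threshold, default 0.
#' @return a [masked_grid] carrying the image affine.
#' @export
read_mask_nifti <- function(path, threshold = 0) {
  if (!file.exists(path)) stop("configuration error: mask file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)
  masked_grid(array(as.array(img) > threshold, dim = dim(img)[1:3]), aff)
}

#' Write an in-mask statistic vector as a NIfTI volume
#'
#' Out-of-mask voxels are written as `background` (default 0). The grid's
#' affine and dims are preserved.
#'
#' @param values length-N numeric vector aligned with the grid's in-mask
#'   ordering.
#' @param grid a [masked_grid].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param background value for out-of-mask voxels.
#' @export
write_map_nifti <- function(values, grid, path, background = 0) {
  stopifnot(length(values) == grid$n_voxels)
  vol <- array(background, dim = grid$dims)
  vol[grid$mask] <- values
  img <- RNifti::asNifti(vol)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Synthetic ellipsoid mask grid
#'
#' A small brain-like sampling space for simulation and tests: an ellipsoid
#' mask centred in a regular lattice. The default (30^3 voxels of 2mm,
#' semi-axes 24 x 26 x 22 mm) gives a grid on which a full model fit runs in
#' seconds.
#'
#' @param dims lattice dimensions (voxels per axis).
#' @param voxel_mm voxel size in mm (isotropic).
#' @param semiaxes_mm ellipsoid semi-axes in mm.
#' @return a [masked_grid]. The affine centres mm (0,0,0) at the lattice
#'   midpoint with positive voxel steps.
#' @export
synthetic_ellipsoid_grid <- function(dims = c(30L, 30L, 30L), voxel_mm = 2,
                                     semiaxes_mm = c(24, 26, 22)) {
  dims <- as.integer(dims)
  off <- -voxel_mm * (dims - 1) / 2
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- off
  cx <- affine[1, 1] * (0:(dims[1] - 1)) + off[1]
  cy <- affine[2, 2] * (0:(dims[2] - 1)) + off[2]
  cz <- affine[3, 3] * (0:(dims[3] - 1)) + off[3]
  d2 <- outer(outer((cx / semiaxes_mm[1])^2, (cy / semiaxes_mm[2])^2, `+`),
              (cz / semiaxes_mm[3])^2, `+`)
  masked_grid(d2 <= 1, affine)
}
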