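#' Read a foci table
#'
#' Reads a delimited table of reported activation peaks, one row per focus,
#' with a study identifier and x, y, z coordinates in millimetres.
#'
#' @param path path to a TSV/CSV file.
#' @param study_col,x_col,y_col,z_col column names.
#' @param sep field separator; `NULL` picks tab for `.tsv` and comma for
#'   `.csv`.
#' @param space_tag coordinate-space label attached to the result (no
#'   conversion is performed; coordinates are assumed to be in the target
#'   grid's space already).
#' @return data.frame of class `foci_table` with columns `study`, `x`, `y`,
#'   `z`.
#' @export
read_foci <- function(path, study_col = "study", x_col = "x", y_col = "y",
                      z_col = "z", sep = NULL, space_tag = "MNI") {
  if (!file.exists(path)) stop("configuration error: foci file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  need <- c(study_col, x_col, y_col, z_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop("configuration error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  foci_table(raw[[study_col]],
             parse_coord(raw[[x_col]], x_col),
             parse_coord(raw[[y_col]], y_col),
             parse_coord(raw[[z_col]], z_col),
             space_tag = space_tag)
}

parse_coord <- function(v, name) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.finite(out))
  if (length(bad) > 0)
    stop("parse error: non-numeric ", name, " coordinate at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  out
}

#' Construct a foci table from vectors
#'
#' @param study study identifiers (non-empty labels).
#' @param x,y,z mm coordinates.
#' @param space_tag coordinate-space label.
#' @return data.frame of class `foci_table`.
#' @export
foci_table <- function(study, x, y, z, space_tag = "MNI") {
  study <- as.character(study)
  if (length(study) > 0 && any(!nzchar(study) | is.na(study)))
    stop("parse error: empty study identifier")
  if (!all(is.finite(c(x, y, z))) && length(x) > 0)
    stop("parse error: non-finite coordinate")
  df <- data.frame(study = study, x = as.numeric(x), y = as.numeric(y),
                   z = as.numeric(z), stringsAsFactors = FALSE)
  attr(df, "space_tag") <- space_tag
  class(df) <- c("foci_table", class(df))
  df
}

#' Reduce foci to the sufficient statistics of the factorized likelihoods
#'
#' Maps each focus to the voxel lattice, removes out-of-mask foci, clamps the
#' per-(study, voxel) multiplicity to one focus (coordinate rounding can land
#' two reported peaks of one study in the same voxel, but the model assumes
#' voxelwise counts of 0 or 1), and computes the per-voxel sums over studies
#' and per-study sums over voxels on which every model objective operates.
#'
#' @param foci a [foci_table] (or any data.frame with `study`, `x`, `y`, `z`).
#' @param grid a [masked_grid].
#' @param study_levels optional character vector fixing the study ordering;
#'   defaults to order of first appearance. Studies listed here but absent
#'   from `foci` contribute zero counts.
#' @return object of class `cbmr_data` with elements `M`, `N`, `y_voxel`
#'   (length-N per-voxel foci sums), `y_study` (named length-M per-study
#'   sums), `total_foci`, `incidence` (sparse M x N 0/1 matrix of per-study
#'   per-voxel counts), `grid`, and `report` (foci removed / clamped).
#' @export
foci_to_counts <- function(foci, grid, study_levels = NULL) {
  stopifnot(inherits(grid, "masked_grid"))
  if (is.null(study_levels)) study_levels <- unique(as.character(foci$study))
  study <- factor(as.character(foci$study), levels = study_levels)
  if (anyNA(study)) stop("alignment error: foci study id not in study_levels")
  M <- length(study_levels)
  N <- grid$n_voxels
  if (nrow(foci) == 0L)
    stop("empty-dataset error: no foci")
  mapped <- mm_to_voxel(as.matrix(foci[, c("x", "y", "z")]), grid)
  keep <- mapped$in_mask
  n_removed <- sum(!keep)
  si <- as.integer(study)[keep]
  vi <- mapped$index[keep]
  # clamp multiplicity: at most one focus per (study, voxel)
  key <- paste(si, vi)
  dup <- duplicated(key)
  n_clamped <- sum(dup)
  si <- si[!dup]; vi <- vi[!dup]
  if (length(vi) == 0L)
    stop("empty-dataset error: every focus removed by masking")
  inc <- Matrix::sparseMatrix(i = si, j = vi, x = 1, dims = c(M, N))
  y_voxel <- as.numeric(Matrix::colSums(inc))
  y_study <- as.numeric(Matrix::rowSums(inc))
  names(y_study) <- study_levels
  structure(
    list(M = M, N = N, y_voxel = y_voxel, y_study = y_study,
         total_foci = length(vi), incidence = inc, grid = grid,
         report = list(n_input = nrow(foci), n_out_of_mask = n_removed,
                       n_clamped = n_clamped)),
    class = "cbmr_data")
}

#' Assemble a dataset directly from sufficient statistics
#'
#' Used by the simulation generators, which produce per-voxel and per-study
#' sums without a foci table.
#' @keywords internal
cbmr_data_from_counts <- function(y_voxel, y_study, grid, incidence = NULL) {
  stopifnot(length(y_voxel) == grid$n_voxels,
            abs(sum(y_voxel) - sum(y_study)) < 1e-8)
  structure(
    list(M = length(y_study), N = grid$n_voxels,
         y_voxel = as.numeric(y_voxel), y_study = as.numeric(y_study),
         total_foci = as.integer(round(sum(y_voxel))), incidence = incidence,
         grid = grid,
         report = list(n_input = sum(y_voxel), n_out_of_mask = 0L,
                       n_clamped = 0L)),
    class = "cbmr_data")
}

#' @export
print.cbmr_data <- function(x, ...) {
  cat("cbmr_data: M =", x$M, "studies, N =", x$N, "voxels,",
      x$total_foci, "foci\n")
  invisible(x)
}

#' Read a study-level covariate table
#'
#' @param path TSV/CSV file keyed by a study-id column.
#' @param study_col study-id column name.
#' @param sep field separator; `NULL` infers from the extension.
#' @return data.frame with a `study` column plus covariates.
#' @export
read_covariates <- function(path, study_col = "study", sep = NULL) {
  if (!file.exists(path)) stop("configuration error: covariate file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tbl <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!study_col %in% names(tbl))
    stop("configuration error: missing study-id column '", study_col, "'")
  names(tbl)[names(tbl) == study_col] <- "study"
  tbl$study <- as.character(tbl$study)
  tbl
}

#' Build a mean-zero study-level covariate matrix
#'
#' Covariate rows are matched to the dataset's study ordering by study id, not
#' by row order, to prevent silent misalignment. Transforms are applied in
#' the order square-root (if requested), then centering, then standardization
#' to unit sample SD (if requested). The model is identifiable only when each
#' covariate column has mean zero, letting the spatial basis capture the
#' overall level, so centering is always applied.
#'
#' @param table data.frame with a `study` column and covariate columns.
#' @param study_ids character vector giving the required study ordering
#'   (e.g. `names(data$y_study)`).
#' @param transforms named list mapping covariate column names to a character
#'   vector of transforms among `"sqrt"`, `"standardize"`. Columns not listed
#'   are centered only. `NULL` selects all non-study columns, centered and
#'   standardized.
#' @return M x R numeric matrix with attributes `transform_record` and
#'   `names`; columns have mean zero. R = 0 (no covariates) yields a valid
#'   M x 0 matrix.
#' @export
build_covariates <- function(table, study_ids, transforms = NULL) {
  study_ids <- as.character(study_ids)
  pos <- match(study_ids, table$study)
  if (anyNA(pos))
    stop("alignment error: missing covariate row for study ",
         paste(utils::head(study_ids[is.na(pos)], 5), collapse = ", "))
  vars <- setdiff(names(table), "study")
  if (is.null(transforms)) {
    transforms <- stats::setNames(
      rep(list(c("standardize")), length(vars)), vars)
  }
  use <- names(transforms)
  if (!all(use %in% vars))
    stop("configuration error: unknown covariate column(s): ",
         paste(setdiff(use, vars), collapse = ", "))
  Z <- matrix(0, nrow = length(study_ids), ncol = length(use),
              dimnames = list(study_ids, use))
  record <- character(length(use))
  for (k in seq_along(use)) {
    v <- as.numeric(table[[use[k]]][pos])
    if (anyNA(v)) stop("parse error: NA covariate value in column ", use[k])
    steps <- transforms[[k]]
    applied <- character(0)
    if ("sqrt" %in% steps) {
      if (any(v < 0)) stop("domain error: sqrt of negative covariate ", use[k])
      v <- sqrt(v); applied <- c(applied, "sqrt")
    }
    v <- v - mean(v); applied <- c(applied, "centered")
    if ("standardize" %in% steps) {
      s <- stats::sd(v)
      if (s < 1e-12)
        stop("degenerate-covariate error: zero variance in column ", use[k])
      v <- v / s; applied <- c(applied, "standardized")
    }
    Z[, k] <- v
    record[k] <- paste(applied, collapse = "+")
  }
  attr(Z, "transform_record") <- stats::setNames(record, use)
  Z
}

#' Empty covariate matrix (no study-level covariates)
#'
#' @param M study count.
#' @return M x 0 matrix; downstream models then use a unit study effect.
#' @export
no_covariates <- function(M) matrix(0, nrow = M, ncol = 0)
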