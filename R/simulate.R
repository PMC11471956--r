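#' Sample a model-based homogeneous null dataset
#'
#' Each study's focus count is drawn Poisson with the stated mean (or fixed
#' at `round(mean_foci)` when `fixed_totals`), and foci are placed uniformly
#' over in-mask voxel centres with replacement; per-(study, voxel)
#' multiplicity is then clamped to 1, as in preprocessing of real data.
#'
#' @param grid a [masked_grid].
#' @param M number of studies.
#' @param mean_foci expected foci per study.
#' @param fixed_totals draw exactly `round(mean_foci)` foci per study.
#' @param keep_incidence retain the sparse study x voxel incidence matrix
#'   (needed by [bias_metrics] and [shuffle_empirical_null]).
#' @return a `cbmr_data`. Uses the current RNG state; seed with
#'   [set.seed()] for reproducibility.
#' @export
sample_model_based_null <- function(grid, M, mean_foci, fixed_totals = FALSE,
                                    keep_incidence = FALSE) {
  stopifnot(mean_foci > 0, M >= 1)
  N <- grid$n_voxels
  n_i <- if (fixed_totals) rep(as.integer(round(mean_foci)), M)
         else stats::rpois(M, mean_foci)
  tot <- sum(n_i)
  if (tot == 0L) {
    return(cbmr_data_from_counts(numeric(N), numeric(M), grid,
      incidence = if (keep_incidence)
        Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(M, N)) else NULL))
  }
  vi <- sample.int(N, tot, replace = TRUE)
  si <- rep.int(seq_len(M), n_i)
  dup <- duplicated(paste(si, vi))
  si <- si[!dup]; vi <- vi[!dup]
  inc <- Matrix::sparseMatrix(i = si, j = vi, x = 1, dims = c(M, N))
  cbmr_data_from_counts(as.numeric(Matrix::colSums(inc)),
                        as.numeric(Matrix::rowSums(inc)), grid,
                        incidence = if (keep_incidence) inc else NULL)
}

#' Empirical null by shuffling foci locations
#'
#' Preserves each study's focus count exactly and resamples locations
#' uniformly over in-mask voxels without replacement within each study (so
#' no within-study collisions arise), guaranteeing spatial homogeneity.
#'
#' @param data a `cbmr_data`.
#' @param keep_incidence retain the incidence matrix.
#' @return a `cbmr_data` with the same `y_study` and shuffled `y_voxel`.
#' @export
shuffle_empirical_null <- function(data, keep_incidence = FALSE) {
  N <- data$N
  counts <- round(data$y_study)
  if (any(counts > N))
    stop("impossible-assignment error: a study has more foci than voxels")
  si <- integer(0); vi <- integer(0)
  for (i in seq_len(data$M)) {
    k <- counts[i]
    if (k > 0) {
      si <- c(si, rep.int(i, k))
      vi <- c(vi, sample.int(N, k, replace = FALSE))
    }
  }
  inc <- Matrix::sparseMatrix(i = si, j = vi, x = 1, dims = c(data$M, N))
  cbmr_data_from_counts(as.numeric(Matrix::colSums(inc)), counts, data$grid,
                        incidence = if (keep_incidence) inc else NULL)
}

#' Sample structured data from a fitted or specified generative model
#'
#' Draws per-(study, voxel) counts from the family's generative model --
#' Poisson; independent Gamma-Poisson per (study, voxel) for NB; a single
#' Gamma(1/alpha, 1/alpha) latent multiplier per study then Poisson for
#' clustered NB -- and clamps counts to 0/1, recording the clamp rate. A
#' clamp rate above 5% signals that the chosen intensities violate the
#' at-most-one-focus-per-voxel regime the models assume.
#'
#' @param beta length-P spline coefficients.
#' @param basis a `spline_basis` over `grid`.
#' @param grid a [masked_grid].
#' @param M number of studies.
#' @param gamma,Z optional covariate effects and matrix.
#' @param family generative family (`"poisson"`, `"nb"`, `"clustered_nb"`).
#' @param alpha dispersion for the NB families; `alpha = 0` falls back to
#'   the Poisson path exactly.
#' @param keep_incidence retain the incidence matrix.
#' @return a `cbmr_data` with attribute `clamp_rate`.
#' @export
sample_structured <- function(beta, basis, grid, M, gamma = numeric(0),
                              Z = NULL, family = "poisson", alpha = 0,
                              keep_incidence = FALSE) {
  stopifnot(family %in% c("poisson", "nb", "clustered_nb"), alpha >= 0)
  if (alpha == 0) family <- "poisson"
  comp <- intensity(beta, gamma, basis, Z, M = M)
  N <- grid$n_voxels
  si <- vector("list", M); vi <- vector("list", M)
  n_clamped <- 0L; n_raw <- 0L
  lam_study <- if (family == "clustered_nb")
    stats::rgamma(M, shape = 1 / alpha, rate = 1 / alpha) else rep(1, M)
  for (i in seq_len(M)) {
    mu_i <- comp$mu_x * comp$mu_z[i] * lam_study[i]
    y <- if (family == "nb")
      stats::rpois(N, stats::rgamma(N, shape = 1 / alpha, rate = 1 / (alpha * mu_i)))
    else stats::rpois(N, mu_i)
    n_raw <- n_raw + sum(y)
    n_clamped <- n_clamped + sum(pmax(y - 1L, 0L))
    hit <- which(y > 0)
    si[[i]] <- rep.int(i, length(hit)); vi[[i]] <- hit
  }
  si <- unlist(si); vi <- unlist(vi)
  inc <- Matrix::sparseMatrix(i = si, j = vi, x = 1, dims = c(M, N))
  out <- cbmr_data_from_counts(as.numeric(Matrix::colSums(inc)),
                               as.numeric(Matrix::rowSums(inc)), grid,
                               incidence = if (keep_incidence) inc else NULL)
  clamp_rate <- if (n_raw > 0) n_clamped / n_raw else 0
  if (clamp_rate > 0.05)
    warning("clamp rate ", signif(100 * clamp_rate, 3),
            "% exceeds 5%: the generative regime violates the counts <= 1 ",
            "assumption")
  attr(out, "clamp_rate") <- clamp_rate
  out
}

#' Monte-Carlo null calibration experiment
#'
#' Repeats: sample a homogeneous null dataset, fit the requested family,
#' compute voxelwise homogeneity p-values, and record (i) the uncorrected
#' rejection rate at `p < 0.05`, (ii) whether Benjamini-Hochberg FDR control
#' at level `q` produces any rejection, before and after p-value truncation
#' at `truncation_floor`. Ordered -log10 p-values are aggregated into a P-P
#' summary (mean and SD at each order index across realizations, with a
#' pointwise band at 1.96 SD). Realizations whose fit fails to converge are
#' recorded and excluded from the summaries, never silently dropped.
#'
#' @param grid a [masked_grid].
#' @param M studies per realization.
#' @param mean_foci expected foci per study.
#' @param family fitted family.
#' @param n_realizations number of Monte-Carlo realizations.
#' @param spacing_mm knot spacing for the fitted basis.
#' @param mode `"model_based"` ([sample_model_based_null]) or
#'   `"empirical_shuffle"` (requires `template_data`).
#' @param template_data a `cbmr_data` whose per-study counts are preserved
#'   under shuffling (empirical mode only).
#' @param q FDR level.
#' @param truncation_floor p-value truncation floor.
#' @param seed integer seed; every realization derives its RNG stream from
#'   it, so identical configurations reproduce bit-identically.
#' @param basis optionally, a prebuilt `spline_basis` for `grid`.
#' @return object of class `cbmr_null_experiment`: `records` (one row per
#'   realization: seed, convergence, uncorrected rejection rate, BH
#'   rejection counts before/after truncation), `fdr_failure_rate_before`,
#'   `fdr_failure_rate_after`, `rejection_rate_005`, `pp` (ordered-index
#'   mean/SD of -log10 p), `n_excluded`.
#' @export
run_null_experiment <- function(grid, M, mean_foci, family = "nb",
                                n_realizations = 20L, spacing_mm = 12,
                                mode = c("model_based", "empirical_shuffle"),
                                template_data = NULL, q = 0.05,
                                truncation_floor = 1e-3, seed = 1L,
                                basis = NULL) {
  mode <- match.arg(mode)
  if (is.null(basis)) basis <- build_basis(grid, knot_config(spacing_mm))
  N <- grid$n_voxels
  recs <- vector("list", n_realizations)
  neglog <- matrix(NA_real_, nrow = n_realizations, ncol = N)
  for (r in seq_len(n_realizations)) {
    set.seed(seed + r - 1L)
    data <- if (mode == "model_based")
      sample_model_based_null(grid, M, mean_foci)
    else shuffle_empirical_null(template_data)
    rec <- list(realization = r, seed = seed + r - 1L, converged = NA,
                n_foci = data$total_foci, rej_rate = NA_real_,
                n_bh_before = NA_integer_, n_bh_after = NA_integer_,
                error = NA_character_)
    res <- tryCatch({
      fit <- fit_cbmr(data, basis, family = family)
      maps <- suppressWarnings(
        homogeneity_wald(fit, data, q = q,
                         truncation_floor = truncation_floor))
      list(fit = fit, maps = maps)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
      rec$converged <- FALSE
    } else {
      rec$converged <- res$fit$converged
      p <- res$maps$p
      rec$rej_rate <- mean(p < 0.05, na.rm = TRUE)
      rec$n_bh_before <- bh_fdr(p, q = q)$n_reject
      rec$n_bh_after <- sum(res$maps$fdr_mask, na.rm = TRUE)
      if (rec$converged)
        neglog[r, ] <- sort(-log10(pmax(p, .Machine$double.xmin)),
                            decreasing = TRUE, na.last = TRUE)
    }
    recs[[r]] <- rec
  }
  records <- do.call(rbind, lapply(recs, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  use <- which(records$converged %in% TRUE)
  n_excluded <- n_realizations - length(use)
  pp_mean <- colMeans(neglog[use, , drop = FALSE], na.rm = TRUE)
  pp_sd <- apply(neglog[use, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  structure(
    list(records = records,
         fdr_failure_rate_before = mean(records$n_bh_before[use] > 0),
         fdr_failure_rate_after = mean(records$n_bh_after[use] > 0),
         rejection_rate_005 = mean(records$rej_rate[use]),
         pp = list(index = seq_len(N), mean = pp_mean, sd = pp_sd,
                   lower = pp_mean - 1.96 * pp_sd,
                   upper = pp_mean + 1.96 * pp_sd,
                   expected = -log10(seq_len(N) / (N + 1))),
         n_excluded = n_excluded, family = family, M = M,
         mean_foci = mean_foci, q = q,
         truncation_floor = truncation_floor, seed = seed),
    class = "cbmr_null_experiment")
}

#' @export
print.cbmr_null_experiment <- function(x, ...) {
  cat("cbmr_null_experiment (", x$family, "): ", nrow(x$records),
      " realizations, M = ", x$M, ", mean foci = ", x$mean_foci, "\n",
      "  FDR failure rate before/after truncation: ",
      signif(100 * x$fdr_failure_rate_before, 3), "% / ",
      signif(100 * x$fdr_failure_rate_after, 3), "%\n",
      "  uncorrected rejection rate at 0.05: ",
      signif(100 * x$rejection_rate_005, 3), "%\n", sep = "")
  if (x$n_excluded > 0)
    cat("  ", x$n_excluded, "non-converged realization(s) excluded\n")
  invisible(x)
}
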