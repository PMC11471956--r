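#' Homogeneous null rate
#'
#' Under spatial homogeneity every per-(study, voxel) rate equals
#' `mu0 = total_foci / (M * N)`; `eta0 = log(mu0)`.
#'
#' @param data a `cbmr_data`.
#' @return list with `mu0` and `eta0`.
#' @export
homogeneity_null <- function(data) {
  if (data$total_foci <= 0) stop("undefined null: zero foci")
  mu0 <- data$total_foci / (data$M * data$N)
  list(mu0 = mu0, eta0 = log(mu0))
}

# invert the observed information restricted to its well-determined
# subspace; returns the covariance of the full parameter vector plus the
# near-null-space basis (columns) used to flag unstable voxels
robust_cov <- function(I, tol = 1e-10) {
  e <- eigen((I + t(I)) / 2, symmetric = TRUE)
  lmax <- max(abs(e$values), .Machine$double.eps)
  ok <- e$values > tol * lmax
  singular <- any(!ok)
  cov <- e$vectors[, ok, drop = FALSE] %*%
    (t(e$vectors[, ok, drop = FALSE]) / e$values[ok])
  list(cov = cov, singular = singular,
       null_basis = e$vectors[, !ok, drop = FALSE])
}

#' Delta-method standard errors of the spatial intensity
#'
#' `Var(eta_x[j]) = x_j' Cov(beta) x_j` from the beta block of the inverse
#' observed information; `SE(mu_x[j]) = mu_x[j] * SE(eta_x[j])` by the delta
#' method for the exponential link. If the information is singular (a regime
#' arising in low-foci data where coefficients diverge in zero-foci
#' regions), the inverse is taken on the well-determined subspace and voxels
#' whose basis row loads on the null space get `NaN` standard errors, with a
#' dataset-level warning -- deflated variances are never substituted.
#'
#' @param fit a `cbmr_fit`.
#' @return list with `se_eta`, `se_mu` (length-N vectors) and `singular`
#'   flag.
#' @export
spatial_se <- function(fit) {
  P <- fit$info_layout[["beta"]]
  rc <- robust_cov(fit$info)
  cov_bb <- rc$cov[seq_len(P), seq_len(P), drop = FALSE]
  X <- fit$basis$X
  var_eta <- Matrix::rowSums((X %*% cov_bb) * X)
  var_eta <- as.numeric(var_eta)
  bad <- var_eta < 0
  if (rc$singular) {
    warning("singular observed information; standard errors set to NaN on ",
            "the affected subspace")
    nb <- rc$null_basis[seq_len(P), , drop = FALSE]
    load <- as.numeric(Matrix::rowSums((X %*% nb)^2))
    norm2 <- as.numeric(Matrix::rowSums(X^2))
    bad <- bad | (load > 1e-8 * pmax(norm2, .Machine$double.eps))
  }
  var_eta[bad] <- NaN
  se_eta <- sqrt(var_eta)
  list(se_eta = se_eta, se_mu = fit$mu_x * se_eta, singular = rc$singular)
}

#' Voxelwise Wald tests of spatial homogeneity
#'
#' Signed Z statistics on the log-intensity scale (the default reported map)
#' and the intensity scale:
#' `Z_eta = (eta_x - eta0) / SE(eta_x)`, `Z_mu = (mu_x - mu0) / SE(mu_x)`,
#' asymptotically Gaussian. P-values are two-sided by default; one-sided
#' (activation-only, upper tail) inference is available via `sided`.
#' Voxels with `NaN` standard errors propagate `NaN` Z and are excluded from
#' FDR accounting downstream.
#'
#' @param fit a `cbmr_fit`.
#' @param data the `cbmr_data` the model was fitted to (supplies `mu0`).
#' @param sided `"two"` (default) or `"one"`.
#' @param q FDR level for the Benjamini-Hochberg threshold (default 0.05).
#' @param truncation_floor floor applied to p-values before FDR (default
#'   1e-3); see [truncate_p].
#' @return object of class `cbmr_maps`: length-N vectors `mu_x`, `eta_x`,
#'   `se_mu`, `se_eta`, `z_mu`, `z_eta`, `p` (from `z_eta`), `p_truncated`,
#'   logical `fdr_mask`, plus `mu0`, `eta0`, `bh_cutoff`, `n_truncated`,
#'   `sided`, `q` and the grid.
#' @export
homogeneity_wald <- function(fit, data, sided = c("two", "one"), q = 0.05,
                             truncation_floor = 1e-3) {
  sided <- match.arg(sided)
  null0 <- homogeneity_null(data)
  se <- spatial_se(fit)
  eta_x <- log(fit$mu_x)
  z_eta <- (eta_x - null0$eta0) / se$se_eta
  z_mu <- (fit$mu_x - null0$mu0) / se$se_mu
  p <- if (sided == "two") 2 * stats::pnorm(-abs(z_eta)) else
    stats::pnorm(z_eta, lower.tail = FALSE)
  p[p == 0 & !is.na(p)] <- .Machine$double.xmin  # keep p in (0, 1]
  pt <- truncate_p(p, floor = truncation_floor)
  bh <- bh_fdr(pt, q = q)
  structure(
    list(mu_x = fit$mu_x, eta_x = eta_x, se_mu = se$se_mu,
         se_eta = se$se_eta, z_mu = z_mu, z_eta = z_eta, p = p,
         p_truncated = pt, fdr_mask = bh$reject, bh_cutoff = bh$cutoff,
         n_truncated = attr(pt, "n_truncated"), mu0 = null0$mu0,
         eta0 = null0$eta0, sided = sided, q = q,
         singular = se$singular, grid = data$grid),
    class = "cbmr_maps")
}

#' @export
print.cbmr_maps <- function(x, ...) {
  cat("cbmr_maps: N =", length(x$p), "voxels, mu0 =", signif(x$mu0, 5),
      ",", sum(x$fdr_mask, na.rm = TRUE), "FDR rejections (q =", x$q, ")\n")
  invisible(x)
}

#' Truncate a p-value map
#'
#' Replaces every p-value smaller than `floor` (default 1e-3) with `floor`.
#' Extreme p-values from the asymptotic Wald tests can be anti-conservative;
#' flooring them before Benjamini-Hochberg restores valid (if conservative)
#' FDR control.
#'
#' @param p numeric vector of p-values.
#' @param floor truncation floor in (0, 1).
#' @return the truncated vector, with attribute `n_truncated` counting
#'   replaced entries.
#' @export
truncate_p <- function(p, floor = 1e-3) {
  stopifnot(floor > 0, floor < 1)
  n <- sum(p < floor, na.rm = TRUE)
  out <- pmax(p, floor)
  attr(out, "n_truncated") <- n
  out
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up procedure over the supplied p-values (`NaN` entries are
#' excluded from the ordering and never rejected).
#'
#' @param p p-values in (0, 1].
#' @param q FDR level.
#' @return list with logical `reject`, the realized `cutoff` (largest
#'   rejected p-value; 0 if none), and `n_reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  ok <- which(is.finite(p))
  m <- length(ok)
  reject <- rep(FALSE, length(p))
  cutoff <- 0
  if (m > 0) {
    ord <- order(p[ok])
    ps <- p[ok][ord]
    below <- which(ps <= q * seq_len(m) / m)
    if (length(below) > 0) {
      kmax <- max(below)
      cutoff <- ps[kmax]
      reject[ok[ord[seq_len(kmax)]]] <- TRUE
    }
  }
  list(reject = reject, cutoff = cutoff, n_reject = sum(reject))
}

#' General linear hypothesis test on covariate effects
#'
#' Tests `H0: C gamma = 0` with the Wald statistic
#' `(C g)' (C Cov(g) C')^-1 (C g)`, asymptotically chi-squared with
#' `m = nrow(C)` degrees of freedom; for a single contrast the signed
#' `z = C g / SE` is also returned.
#'
#' @param fit a `cbmr_fit` with covariates.
#' @param C m x R contrast matrix (a vector is taken as one row).
#' @return object of class `cbmr_glh`: `statistic`, `df`, `p`, and `z`
#'   (single contrast only).
#' @export
glh_covariates <- function(fit, C) {
  R <- fit$info_layout[["gamma"]]
  if (R == 0L) stop("contrast error: model has no covariates")
  if (is.null(dim(C))) C <- matrix(C, nrow = 1)
  if (ncol(C) != R) stop("contrast error: C must have ", R, " columns")
  if (any(apply(C, 1, function(r) all(r == 0))))
    stop("contrast error: zero contrast row")
  P <- fit$info_layout[["beta"]]
  rc <- robust_cov(fit$info)
  cov_gg <- rc$cov[P + seq_len(R), P + seq_len(R), drop = FALSE]
  Cg <- as.numeric(C %*% fit$gamma)
  V <- C %*% cov_gg %*% t(C)
  if (rcond(V) < 1e-12) stop("contrast error: rank-deficient contrast covariance")
  stat <- as.numeric(crossprod(Cg, solve(V, Cg)))
  m <- nrow(C)
  structure(
    list(statistic = stat, df = m,
         p = stats::pchisq(stat, df = m, lower.tail = FALSE),
         z = if (m == 1L) Cg / sqrt(V[1, 1]) else NULL,
         contrast = C),
    class = "cbmr_glh")
}

#' @export
print.cbmr_glh <- function(x, ...) {
  cat("GLH: chi2(", x$df, ") = ", signif(x$statistic, 5), ", p = ",
      format(x$p), if (!is.null(x$z)) paste0(", z = ", signif(x$z, 5)),
      "\n", sep = "")
  invisible(x)
}

# Poisson log-likelihood on the summed-count data scale, evaluated at the
# fitted means: sum_j [ Y_j log(m_j) - m_j - lgamma(Y_j + 1) ] with
# m_j = mu_x[j] * sum(mu_z). This is the Poisson objective comparable with
# the NB objective, which models the per-voxel sums.
poisson_loglik_summed <- function(fit) {
  s1 <- sum(fit$mu_z)
  m <- fit$mu_x * s1
  y <- fit$data_summary$y_voxel
  sum(y * log(m) - m) - fit$data_summary$const_lgamma
}

#' Likelihood-ratio test of Poisson against an overdispersed family
#'
#' `lambda = -2 [l(poisson) - l(alternative)]`, referred to chi-squared with
#' one degree of freedom (the dispersion alpha). The two objectives must be
#' on the same data scale: against the NB family (which models per-voxel
#' sums) the Poisson log-likelihood is re-expressed on the summed-count
#' scale; against the clustered NB family both objectives are already
#' complete per-observation log-likelihoods. Note the null value alpha = 0
#' lies on the boundary of the parameter space; the plain chi-squared
#' reference used here is then conservative.
#'
#' @param fit_null a Poisson `cbmr_fit`.
#' @param fit_alt an NB or clustered-NB `cbmr_fit` on the same data and
#'   basis.
#' @return list with `lambda` (floored at 0), `df = 1`, `p`.
#' @export
lrt <- function(fit_null, fit_alt) {
  if (fit_null$family != "poisson")
    stop("comparison error: fit_null must be the poisson fit")
  if (!fit_alt$family %in% c("nb", "clustered_nb"))
    stop("comparison error: fit_alt must be an nb or clustered_nb fit")
  if (fit_null$data_summary$total_foci != fit_alt$data_summary$total_foci ||
      fit_null$basis$P != fit_alt$basis$P)
    stop("comparison error: fits are not on the same data and basis")
  l0 <- if (fit_alt$family == "nb") poisson_loglik_summed(fit_null)
        else fit_null$loglik
  lambda <- max(0, -2 * (l0 - fit_alt$loglik))
  list(lambda = lambda, df = 1L,
       p = stats::pchisq(lambda, df = 1, lower.tail = FALSE))
}

#' Akaike information criterion
#'
#' `AIC = 2k - 2 l(theta_hat)` with `k` counting all free parameters (spline
#' and covariate coefficients plus the dispersion when estimated). Each
#' family's objective carries its own constant convention (see [lrt]), so
#' AIC differences are only meaningful between objectives on the same data
#' scale; `scale` selects the convention for the Poisson family.
#'
#' @param fit a `cbmr_fit` from a likelihood family.
#' @param scale `"native"` (the family's printed objective) or `"summed"`
#'   (Poisson re-expressed on per-voxel sums, comparable with NB).
#' @export
model_aic <- function(fit, scale = c("native", "summed")) {
  scale <- match.arg(scale)
  if (is.na(fit$loglik)) stop("no likelihood for the quasi_poisson family")
  ll <- if (scale == "summed" && fit$family == "poisson")
    poisson_loglik_summed(fit) else fit$loglik
  2 * fit$k - 2 * ll
}

#' Goodness-of-fit bias metrics
#'
#' Three relative-bias summaries of a fitted intensity:
#' \enumerate{
#'   \item intensity-sum bias: `|sum_j mu_hat[.,j] - total_foci| /
#'     total_foci`;
#'   \item per-axis SD bias: relative absolute difference between the SD of
#'     the fitted intensity's marginal coordinate distribution (voxel
#'     centres weighted by fitted intensity) and the empirical
#'     foci-coordinate SD (weighted by observed counts), for x, y, z;
#'   \item voxelwise variance bias: over voxels with at least one focus, the
#'     mean relative absolute difference between the family's model variance
#'     of a per-study count (`mu`, `mu + alpha mu^2`, or `theta mu`) and the
#'     empirical mean squared residual `(Y_ij - mu_hat_ij)^2` over studies
#'     (which requires the per-study incidence retained by
#'     [foci_to_counts]).
#' }
#'
#' @param fit a `cbmr_fit`.
#' @param data the fitted `cbmr_data`.
#' @return list with `bias_intensity_sum`, `bias_sd` (named x/y/z),
#'   `bias_variance` (NA when the dataset carries no incidence matrix).
#' @export
bias_metrics <- function(fit, data) {
  if (data$total_foci <= 0) stop("undefined: zero foci")
  s1 <- sum(fit$mu_z)
  mu_dot <- fit$mu_x * s1  # expected per-voxel sum over studies
  bias_sum <- abs(sum(mu_dot) - data$total_foci) / data$total_foci
  coords <- vapply(1:3, function(a) {
    pos <- data$grid$voxel_lattice[, a]
    data$grid$affine[a, a] * pos + data$grid$affine[a, 4]
  }, numeric(data$N))
  wsd <- function(x, w) {
    w <- w / sum(w)
    m <- sum(w * x)
    sqrt(sum(w * (x - m)^2))
  }
  bias_sd <- vapply(1:3, function(a)
    abs(wsd(coords[, a], mu_dot) - wsd(coords[, a], data$y_voxel)) /
      wsd(coords[, a], data$y_voxel), numeric(1))
  names(bias_sd) <- c("x", "y", "z")
  bias_var <- NA_real_
  if (!is.null(data$incidence)) {
    vox <- which(data$y_voxel >= 1)
    mu_x <- fit$mu_x[vox]
    # empirical mean over studies of (Y_ij - mu_ij)^2, factorized:
    # sum_i (Y_ij - mu_x_j mu_z_i)^2 = Y_.j - 2 mu_x_j sum_i Y_ij mu_z_i
    #                                  + mu_x_j^2 sum_i mu_z_i^2
    yz <- as.numeric(Matrix::crossprod(data$incidence[, vox, drop = FALSE],
                                       fit$mu_z))
    s2 <- sum(fit$mu_z^2)
    emp <- (data$y_voxel[vox] - 2 * mu_x * yz + mu_x^2 * s2) / data$M
    model_var <- switch(fit$family,
      poisson = mu_x * s1 / data$M,
      nb = (mu_x * s1 + fit$alpha * mu_x^2 * s2) / data$M,
      clustered_nb = (mu_x * s1 + fit$alpha * mu_x^2 * s2) / data$M,
      quasi_poisson = fit$theta * mu_x * s1 / data$M)
    bias_var <- mean(abs(model_var - emp) / emp)
  }
  list(bias_intensity_sum = bias_sum, bias_sd = bias_sd,
       bias_variance = bias_var)
}

#' Range of attainable -log10 p-values under a discrete null
#'
#' With N voxelwise p-values the expected null order statistics span
#' `-log10(N/(N+1))` (approximately 0) to `-log10(1/(N+1))`; the upper end
#' is the smallest attainable expected p-value index on a P-P plot.
#'
#' @param N number of tests (in-mask voxels).
#' @return named vector with `min` and `max` of the expected -log10 p range.
#' @export
null_neglog10_range <- function(N) {
  c(min = -log10(N / (N + 1)), max = log10(N + 1))
}
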