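#' Fitting configuration
#'
#' @param max_iter iteration cap (default 1000).
#' @param tol relative objective-change tolerance (default 1e-8).
#' @param grad_tol max-absolute-gradient tolerance (default 1e-5).
#' @param verbose print iteration progress.
#' @export
fit_config <- function(max_iter = 1000L, tol = 1e-8, grad_tol = 1e-5,
                       verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1)
  list(max_iter = as.integer(max_iter), tol = tol, grad_tol = grad_tol,
       verbose = verbose)
}

# deterministic, scale-aware initialization: constant spatial field matching
# the observed mean rate; covariate effects and log-dispersion start at 0
init_params <- function(data, obj) {
  rate <- max(data$total_foci, 0.5) / (data$M * data$N)
  c(rep(log(rate), obj$P), numeric(obj$R), if (obj$has_alpha) 0)
}

#' Fit a coordinate-based meta-regression model
#'
#' Dispatches to the optimizer matched to the family: Fisher scoring for the
#' Poisson likelihood without covariates, L-BFGS for any likelihood family
#' (required once covariates or an NB dispersion enter), and IRLS for the
#' Quasi-Poisson model. Dispersion is optimized as `log(alpha)` to keep it
#' positive without constraints. The observed Fisher information at the
#' optimum is recomputed from the analytic score (closed form for Poisson,
#' central finite differences of the gradient otherwise), never taken from
#' the optimizer's internal approximation.
#'
#' @param data a `cbmr_data` from [foci_to_counts] or a simulation generator.
#' @param basis a `spline_basis` from [build_basis].
#' @param Z optional M x R mean-zero covariate matrix ([build_covariates]);
#'   `NULL` means no covariates.
#' @param family one of `"poisson"`, `"nb"`, `"clustered_nb"`,
#'   `"quasi_poisson"`.
#' @param method `"auto"` (Fisher scoring for covariate-free Poisson,
#'   L-BFGS otherwise), `"fisher"`, `"lbfgs"`, or `"irls"` (Quasi-Poisson
#'   only).
#' @param config a [fit_config].
#' @return object of class `cbmr_fit`: coefficient vectors `beta`, `gamma`,
#'   dispersion (`alpha` or `theta`), `loglik` (maximized objective, `NA` for
#'   Quasi-Poisson), `k` (free-parameter count), `converged`, `n_iter`,
#'   `info` (observed information over the free parameters, layout
#'   beta, gamma, log-alpha), `notes`, plus references to `basis`, `Z` and
#'   dataset summaries used by the inference functions.
#' @export
fit_cbmr <- function(data, basis, Z = NULL, family = c("poisson", "nb",
                     "clustered_nb", "quasi_poisson"),
                     method = "auto", config = fit_config()) {
  family <- match.arg(family)
  R <- if (is.null(Z)) 0L else ncol(Z)
  if (family == "quasi_poisson")
    return(fit_irls_quasi_poisson(data, basis, Z, config))
  if (method == "auto")
    method <- if (family == "poisson" && R == 0L) "fisher" else "lbfgs"
  if (method == "fisher") {
    if (family != "poisson" || R > 0L)
      stop("Fisher scoring is implemented for the covariate-free Poisson model")
    fit_fisher_scoring(data, basis, config)
  } else {
    fit_lbfgs(data, basis, Z, family, config)
  }
}

#' Fisher scoring for the covariate-free Poisson model
#'
#' Iterates `beta <- beta + I^-1 score` with the closed-form Poisson blocks
#' (`score = X'(Y_voxel - M mu_x)`, `I = M X' diag(mu_x) X`), halving the
#' step whenever the objective would decrease. A persistently singular
#' information matrix is solved by pseudo-inverse with a recorded warning.
#'
#' @inheritParams fit_cbmr
#' @export
fit_fisher_scoring <- function(data, basis, config = fit_config()) {
  obj <- family_objective("poisson", data, basis, NULL)
  beta <- init_params(data, obj)
  ll <- obj$ll(beta)
  M <- data$M
  notes <- character(0)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iter) {
    it <- it + 1L
    mu_x <- exp(pmin(pmax(as.numeric(basis$X %*% beta), -LINPRED_CLIP), LINPRED_CLIP))
    score <- as.numeric(Matrix::crossprod(basis$X, data$y_voxel - M * mu_x))
    info <- M * as.matrix(Matrix::crossprod(basis$X, basis$X * mu_x))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      notes <- union(notes, "singular information; pseudo-inverse step")
      step <- as.numeric(MASS::ginv(info) %*% score)
    }
    # step-halving: never accept a decrease of the objective
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- obj$ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; ll_new <- ll; break }
    }
    moved <- abs(ll_new - ll) <= config$tol * (abs(ll) + 1)
    beta <- cand; ll <- ll_new
    if (config$verbose) message("iter ", it, " loglik ", format(ll))
    if (moved && max(abs(obj$gr(beta))) <= config$grad_tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    if (moved && lam < 1e-10) break
  }
  g <- obj$gr(beta)
  if (!converged && max(abs(g)) <= config$grad_tol * (1 + abs(ll)))
    converged <- TRUE
  new_cbmr_fit(family = "poisson", par = beta, loglik = ll,
               converged = converged, n_iter = it, notes = notes,
               data = data, basis = basis, Z = NULL, obj = obj)
}

#' Quasi-Newton (L-BFGS) fitting for likelihood families
#'
#' Maximizes the factorized objective over `(beta, gamma, log alpha)` using
#' `optim(method = "L-BFGS-B")` with the analytic score (covariate block by
#' central differences for the NB family). `log alpha` is box-bounded in
#' [-20, 10]; at the lower bound the NB families are numerically Poisson.
#'
#' @inheritParams fit_cbmr
#' @export
fit_lbfgs <- function(data, basis, Z = NULL,
                      family = c("poisson", "nb", "clustered_nb"),
                      config = fit_config()) {
  family <- match.arg(family)
  obj <- family_objective(family, data, basis, Z)
  par0 <- init_params(data, obj)
  lower <- rep(-Inf, obj$n_par); upper <- rep(Inf, obj$n_par)
  if (obj$has_alpha) {
    lower[obj$n_par] <- -20
    upper[obj$n_par] <- 10
  }
  res <- stats::optim(par0, fn = function(p) -obj$ll(p),
                      gr = function(p) -obj$gr(p),
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = config$max_iter,
                                     factr = max(config$tol / 1e-8, 10),
                                     pgtol = 0))
  # optim can stop with an "abnormal line search" code once the objective
  # is flat to rounding; accept the iterate when the score is negligible
  # (interior gradient components only -- a bound-active log-alpha is fine)
  g <- obj$gr(res$par)
  if (obj$has_alpha && res$par[obj$n_par] <= lower[obj$n_par] + 1e-8)
    g[obj$n_par] <- 0
  grad_ok <- max(abs(g)) <= config$grad_tol * (1 + abs(res$value))
  converged <- res$convergence == 0 || grad_ok
  notes <- if (!converged)
    paste0("L-BFGS did not converge (code ", res$convergence, "): ",
           res$message) else character(0)
  new_cbmr_fit(family = family, par = res$par, loglik = -res$value,
               converged = converged, n_iter = res$counts[1],
               notes = notes, data = data, basis = basis, Z = Z, obj = obj)
}

#' IRLS fitting for the Quasi-Poisson model
#'
#' Alternates the factorized updates on the sufficient statistics: the
#' spatial block is the reweighted update
#' `beta <- beta + (X' W X)^-1 X' (Y_voxel - mu*)` with working weights
#' `W = diag(mu*)` (`theta` cancels from the fixed point and is profiled
#' out afterwards), where `mu* = exp(X beta)` absorbs the total study effect;
#' the covariate block runs the same update for `Y_study` on `Z` augmented
#' with an internal intercept that absorbs the overall per-study rate (the
#' intercept is discarded; covariates are mean-zero so `gamma` is unchanged
#' by this augmentation). After convergence the reported `beta` is shifted
#' by `-log(sum(exp(Z gamma)))` so that, as in the likelihood families, the
#' spatial field is the per-study per-voxel rate. `theta` is estimated by
#' the Pearson statistic over voxels divided by the residual degrees of
#' freedom `N - P`; the stored covariance of `beta` is the inverse weighted
#' cross-product scaled by `theta`.
#'
#' @inheritParams fit_cbmr
#' @export
fit_irls_quasi_poisson <- function(data, basis, Z = NULL,
                                   config = fit_config()) {
  N <- data$N; P <- basis$P
  R <- if (is.null(Z)) 0L else ncol(Z)
  notes <- character(0)
  # spatial block on per-voxel sums
  beta <- rep(log(max(data$total_foci, 0.5) / N), P)
  conv_b <- FALSE
  dev_old <- Inf
  for (it in seq_len(config$max_iter)) {
    mu <- exp(pmin(pmax(as.numeric(basis$X %*% beta), -LINPRED_CLIP), LINPRED_CLIP))
    w <- pmax(mu, 1e-10)
    if (any(mu < 1e-10))
      notes <- union(notes, "IRLS weights floored at 1e-10 for near-zero intensities")
    XtWX <- as.matrix(Matrix::crossprod(basis$X, basis$X * w))
    score <- as.numeric(Matrix::crossprod(basis$X, data$y_voxel - mu))
    step <- tryCatch(solve(XtWX, score), error = function(e) {
      notes <<- union(notes, "singular IRLS cross-product; pseudo-inverse step")
      as.numeric(MASS::ginv(XtWX) %*% score)
    })
    beta <- beta + step
    dev <- sum((data$y_voxel - mu)^2 / w)
    if (is.finite(dev) && abs(dev - dev_old) <= config$tol * (abs(dev) + 1) &&
        max(abs(step)) < 1e-6) { conv_b <- TRUE; break }
    dev_old <- dev
  }
  n_iter <- it
  # covariate block on per-study sums, internal intercept absorbs the scale
  gamma <- numeric(R)
  conv_g <- TRUE
  if (R > 0) {
    Za <- cbind(1, Z)
    ga <- c(log(max(mean(data$y_study), 0.5)), numeric(R))
    conv_g <- FALSE
    for (it in seq_len(config$max_iter)) {
      mz <- exp(pmin(pmax(as.numeric(Za %*% ga), -LINPRED_CLIP), LINPRED_CLIP))
      wz <- pmax(mz, 1e-10)
      step <- tryCatch(
        solve(crossprod(Za, Za * wz), crossprod(Za, data$y_study - mz)),
        error = function(e) NULL)
      if (is.null(step)) {
        notes <- union(notes, "singular covariate cross-product")
        break
      }
      ga <- ga + as.numeric(step)
      if (max(abs(step)) < 1e-8) { conv_g <- TRUE; break }
    }
    gamma <- ga[-1]
  }
  mu_z <- if (R > 0) exp(as.numeric(Z %*% gamma)) else rep(1, data$M)
  s1 <- sum(mu_z)
  beta_rep <- beta - log(s1)  # per-study per-voxel spatial rate
  # profile theta via the Pearson statistic on the voxel sums
  mu_fit <- exp(pmin(pmax(as.numeric(basis$X %*% beta), -LINPRED_CLIP), LINPRED_CLIP))
  df_res <- max(N - P, 1L)
  theta <- sum((data$y_voxel - mu_fit)^2 / pmax(mu_fit, 1e-10)) / df_res
  mu_w <- pmax(mu_fit, 1e-10)
  XtWX <- as.matrix(Matrix::crossprod(basis$X, basis$X * mu_w))
  fit <- structure(
    list(family = "quasi_poisson", beta = beta_rep, gamma = gamma,
         alpha = NULL, theta = theta, loglik = NA_real_,
         k = P + R + 1L, converged = conv_b && conv_g, n_iter = n_iter,
         info = XtWX / theta, info_layout = c(beta = P, gamma = 0L, lalpha = 0L),
         notes = notes, basis = basis, Z = Z,
         data_summary = fit_data_summary(data),
         mu_x = exp(pmin(pmax(as.numeric(basis$X %*% beta_rep),
                              -LINPRED_CLIP), LINPRED_CLIP)),
         mu_z = mu_z),
    class = "cbmr_fit")
  fit
}

fit_data_summary <- function(data) {
  list(M = data$M, N = data$N, total_foci = data$total_foci,
       const_lgamma = sum(lgamma(data$y_voxel + 1)),
       y_voxel = data$y_voxel, y_study = data$y_study)
}

new_cbmr_fit <- function(family, par, loglik, converged, n_iter, notes,
                         data, basis, Z, obj) {
  P <- obj$P; R <- obj$R
  beta <- par[seq_len(P)]
  gamma <- if (R > 0) par[P + seq_len(R)] else numeric(0)
  alpha <- if (obj$has_alpha) exp(par[P + R + 1L]) else NULL
  if (obj$has_alpha && par[P + R + 1L] <= -20 + 1e-8)
    notes <- union(notes, "alpha at lower bound (model numerically Poisson)")
  info <- observed_information_par(par, obj, family, data, basis, Z)
  comp <- suppressWarnings(intensity(beta, gamma, basis, Z, M = data$M))
  structure(
    list(family = family, beta = beta, gamma = gamma, alpha = alpha,
         theta = NULL, loglik = loglik, k = obj$n_par,
         converged = converged, n_iter = n_iter,
         info = info, info_layout = c(beta = P, gamma = R,
                                      lalpha = as.integer(obj$has_alpha)),
         notes = notes, basis = basis, Z = Z,
         data_summary = fit_data_summary(data),
         mu_x = comp$mu_x, mu_z = comp$mu_z),
    class = "cbmr_fit")
}

#' @export
print.cbmr_fit <- function(x, ...) {
  cat("cbmr_fit (", x$family, "): P = ", x$info_layout[["beta"]],
      ", R = ", length(x$gamma),
      if (!is.null(x$alpha)) paste0(", alpha = ", signif(x$alpha, 4)),
      if (!is.null(x$theta)) paste0(", theta = ", signif(x$theta, 4)),
      ", loglik = ", format(x$loglik),
      ", converged = ", x$converged, "\n", sep = "")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# observed information at `par`: closed form for Poisson, symmetric central
# finite differences of the analytic gradient otherwise
observed_information_par <- function(par, obj, family, data, basis, Z) {
  P <- obj$P; R <- obj$R
  if (family == "poisson") {
    beta <- par[seq_len(P)]
    gamma <- if (R > 0) par[P + seq_len(R)] else numeric(0)
    comp <- suppressWarnings(intensity(beta, gamma, basis, Z, M = data$M))
    I_bb <- comp$s1 * as.matrix(Matrix::crossprod(basis$X, basis$X * comp$mu_x))
    if (R == 0) return((I_bb + t(I_bb)) / 2)
    Xu <- as.numeric(Matrix::crossprod(basis$X, comp$mu_x))
    vZ <- as.numeric(crossprod(Z, comp$mu_z))
    I_bg <- outer(Xu, vZ)
    I_gg <- comp$U * crossprod(Z, Z * comp$mu_z)
    I <- rbind(cbind(I_bb, I_bg), cbind(t(I_bg), I_gg))
    return((I + t(I)) / 2)
  }
  n <- obj$n_par
  H <- matrix(0, n, n)
  h <- (.Machine$double.eps)^(1/3) * (1 + abs(par))
  for (k in seq_len(n)) {
    pp <- par; pp[k] <- pp[k] + h[k]
    pm <- par; pm[k] <- pm[k] - h[k]
    H[, k] <- (obj$gr(pp) - obj$gr(pm)) / (2 * h[k])
  }
  (-H - t(H)) / 2
}

#' Observed Fisher information of a fitted model
#'
#' Returns the stored observed information (negative Hessian of the
#' objective for likelihood families; the dispersion-scaled weighted
#' cross-product for Quasi-Poisson), recomputed at the optimum. Symmetry is
#' enforced by averaging with the transpose at construction. An indefinite
#' matrix is flagged via the `indefinite` attribute; downstream standard
#' errors refuse negative variances.
#'
#' @param fit a `cbmr_fit`.
#' @export
observed_information <- function(fit) {
  I <- fit$info
  ev <- tryCatch(eigen(I, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA)
  attr(I, "indefinite") <- any(ev < -1e-8 * max(abs(ev), 1))
  I
}

#' @export
logLik.cbmr_fit <- function(object, ...) {
  if (is.na(object$loglik))
    stop("no likelihood for the quasi_poisson family")
  structure(object$loglik, df = object$k, class = "logLik")
}
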