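#' Model families
#'
#' The four stochastic models for voxelwise foci counts:
#' \describe{
#'   \item{poisson}{independent Poisson counts; variance equals mean.}
#'   \item{nb}{independent Negative Binomial counts at each (study, voxel)
#'     with a single dispersion `alpha` shared over studies and voxels;
#'     variance `mu + alpha * mu^2`. The per-voxel sum over studies is
#'     approximated by a moment-matched NB (a sum of NB variates is not NB).}
#'   \item{clustered_nb}{one Gamma(1/alpha, 1/alpha) latent multiplier per
#'     study scales that study's whole intensity; marginally NB at each
#'     voxel with within-study covariance `alpha * mu_ij * mu_ij'`.}
#'   \item{quasi_poisson}{mean model plus the variance function
#'     `V = theta * mu` (theta >= 1); quasi-likelihood, fitted by IRLS.}
#' }
#' @name cbmr_families
#' @keywords internal
NULL

CBMR_FAMILIES <- c("poisson", "nb", "clustered_nb", "quasi_poisson")

LINPRED_CLIP <- 300  # clip linear predictors at +/- this before exp()

#' Factorized intensity components
#'
#' The intensity factorizes as `mu_ij = mu_x[j] * mu_z[i]`: a spatial field
#' `mu_x = exp(X beta)` shared by all studies and a global study effect
#' `mu_z = exp(Z gamma)`. The M x N matrix `mu_ij` is never materialized;
#' everything downstream consumes `mu_x`, `mu_z` and their scalar summaries.
#' Linear predictors are clipped at +/-300 before exponentiation to guard
#' overflow (a warning records any clipping).
#'
#' @param beta length-P spline coefficients.
#' @param gamma length-R covariate coefficients (length 0 when R = 0).
#' @param basis a `spline_basis` (or any object with an `X` matrix).
#' @param Z M x R mean-zero covariate matrix; `NULL` or M x 0 means no
#'   covariates, giving `mu_z` identically 1.
#' @param M study count, required when `Z` is `NULL`.
#' @return list with `mu_x` (length N), `mu_z` (length M), `eta_x = log mu_x`,
#'   and the scalar summaries `s1 = sum(mu_z)`, `s2 = sum(mu_z^2)`,
#'   `U = sum(mu_x)`.
#' @export
intensity <- function(beta, gamma, basis, Z = NULL, M = NULL) {
  if (!all(is.finite(beta)) || !all(is.finite(gamma)))
    stop("numeric error: non-finite parameter")
  eta_x <- as.numeric(basis$X %*% beta)
  if (is.null(Z) || ncol(Z) == 0L) {
    if (is.null(M)) M <- if (is.null(Z)) stop("M required when Z is NULL") else nrow(Z)
    eta_z <- numeric(M)
  } else {
    eta_z <- as.numeric(Z %*% gamma)
  }
  nclip <- sum(abs(eta_x) > LINPRED_CLIP) + sum(abs(eta_z) > LINPRED_CLIP)
  if (nclip > 0)
    warning("clipped ", nclip, " linear predictor value(s) at +/-", LINPRED_CLIP)
  eta_x <- pmin(pmax(eta_x, -LINPRED_CLIP), LINPRED_CLIP)
  eta_z <- pmin(pmax(eta_z, -LINPRED_CLIP), LINPRED_CLIP)
  mu_x <- exp(eta_x); mu_z <- exp(eta_z)
  list(mu_x = mu_x, mu_z = mu_z, eta_x = eta_x,
       s1 = sum(mu_z), s2 = sum(mu_z^2), U = sum(mu_x))
}

#' Factorized Poisson log-likelihood
#'
#' `l = Y_voxel' log(mu_x) + Y_study' log(mu_z) - sum(mu_x) * sum(mu_z)`.
#' Because per-(study, voxel) counts never exceed 1, all `log(Y_ij!)` terms
#' vanish and this is the complete per-observation Poisson log-likelihood:
#' no constants are dropped on the per-(study, voxel) data scale.
#'
#' @param data a `cbmr_data`.
#' @param comp output of [intensity].
#' @return scalar log-likelihood.
#' @export
loglik_poisson <- function(data, comp) {
  sum(data$y_voxel * log(comp$mu_x)) + sum(data$y_study * log(comp$mu_z)) -
    comp$U * comp$s1
}

grad_poisson <- function(data, comp, basis, Z) {
  g_beta <- as.numeric(Matrix::crossprod(basis$X, data$y_voxel - comp$s1 * comp$mu_x))
  g_gamma <- if (!is.null(Z) && ncol(Z) > 0)
    as.numeric(crossprod(Z, data$y_study - comp$U * comp$mu_z)) else numeric(0)
  c(g_beta, g_gamma)
}

#' Moment-matched NB parameters for per-voxel sums
#'
#' A sum of independent NB variates is not NB; the per-voxel sum over studies
#' is approximated by the NB whose first two moments match the convolution
#' exactly. With `mu_ij = mu_x[j] mu_z[i]` the study sums factor out, so the
#' size `r` and the effective dispersion `alpha_prime` are voxel-constant:
#' `r = s1^2 / (alpha s2)`, `p_j = mu_x[j] s2 / (s1/alpha + mu_x[j] s2)`,
#' `alpha_prime = alpha s2 / s1^2`, where `s1 = sum(mu_z)`,
#' `s2 = sum(mu_z^2)`. Computed without any M x N materialization.
#'
#' @param comp output of [intensity].
#' @param alpha NB dispersion, must be > 0.
#' @return list with `r` (scalar size), `p` (length-N success probability),
#'   `alpha_prime`.
#' @export
nb_moment_match <- function(comp, alpha) {
  if (!is.finite(alpha) || alpha <= 0)
    stop("domain error: alpha must be > 0 (use the poisson family for alpha = 0)")
  A <- comp$s1 / alpha
  r <- comp$s1^2 / (alpha * comp$s2)
  denom <- A + comp$mu_x * comp$s2
  list(r = r, p = comp$mu_x * comp$s2 / denom, alpha_prime = alpha * comp$s2 / comp$s1^2)
}

# lgamma(y + r) - lgamma(r) for nonnegative integer y and scalar r > 0,
# stable for huge r (as alpha -> 0 the matched size r diverges and the
# direct lgamma difference loses precision to cancellation)
lgamma_ratio_int <- function(y, r) {
  if (r < 1e8) return(lgamma(y + r) - lgamma(r))
  ymax <- max(y)
  if (ymax == 0) return(numeric(length(y)))
  steps <- c(0, cumsum(log(r + seq_len(ymax) - 1)))
  steps[y + 1]
}

# digamma(y + r) - digamma(r), same regime as lgamma_ratio_int
digamma_ratio_int <- function(y, r) {
  if (r < 1e8) return(digamma(y + r) - digamma(r))
  ymax <- max(y)
  if (ymax == 0) return(numeric(length(y)))
  steps <- c(0, cumsum(1 / (r + seq_len(ymax) - 1)))
  steps[y + 1]
}

#' Factorized Negative Binomial log-likelihood
#'
#' Sum over voxels of the NB log-pmf of the per-voxel foci sum under the
#' moment-matched parameters of [nb_moment_match]. This objective is on the
#' summed-count data scale (it models `Y_voxel`, not the per-study layout);
#' see [lrt] for how it is compared with the Poisson objective.
#'
#' @inheritParams loglik_poisson
#' @param alpha NB dispersion (> 0).
#' @export
loglik_nb <- function(data, comp, alpha) {
  mm <- nb_moment_match(comp, alpha)
  y <- data$y_voxel
  sum(lgamma_ratio_int(y, mm$r) - lgamma(y + 1) +
        mm$r * log1p(-mm$p) + y * ifelse(y > 0, log(mm$p), 0))
}

# gradient of loglik_nb wrt (beta, log alpha); gamma handled numerically
grad_nb_beta_lalpha <- function(data, comp, alpha, basis) {
  A <- comp$s1 / alpha
  r <- comp$s1^2 / (alpha * comp$s2)
  denom <- A + comp$mu_x * comp$s2
  p <- comp$mu_x * comp$s2 / denom
  y <- data$y_voxel
  g_beta <- as.numeric(Matrix::crossprod(basis$X, y - (r + y) * p))
  L_r <- sum(digamma_ratio_int(y, r) + log1p(-p))
  L_A <- sum(r / A - (r + y) / denom)
  g_lalpha <- -r * L_r - A * L_A
  list(g_beta = g_beta, g_lalpha = g_lalpha)
}

#' Factorized Clustered Negative Binomial log-likelihood
#'
#' Study-level Gamma latent effects give the marginal objective
#' `M a log a - M lgamma(a) + sum_i lgamma(Y_i. + a)
#'  - sum_i (Y_i. + a) log(a + mu_i.) + Y_voxel' log mu_x + Y_study' log mu_z`
#' with `a = 1/alpha` and `mu_i. = mu_z[i] * sum(mu_x)`. The
#' `sum log(Y_ij!)` term vanishes because per-(study, voxel) counts are at
#' most 1, so this is the complete log-likelihood on the per-observation
#' scale, directly comparable with [loglik_poisson].
#'
#' @inheritParams loglik_nb
#' @export
loglik_clustered_nb <- function(data, comp, alpha) {
  if (!is.finite(alpha) || alpha <= 0)
    stop("domain error: alpha must be > 0 (use the poisson family for alpha = 0)")
  a <- 1 / alpha
  M <- data$M
  mu_i <- comp$mu_z * comp$U
  M * a * log(a) - M * lgamma(a) + sum(lgamma(data$y_study + a)) -
    sum((data$y_study + a) * log(a + mu_i)) +
    sum(data$y_voxel * log(comp$mu_x)) + sum(data$y_study * log(comp$mu_z))
}

grad_clustered_nb <- function(data, comp, alpha, basis, Z) {
  a <- 1 / alpha
  M <- data$M
  mu_i <- comp$mu_z * comp$U
  w <- (data$y_study + a) * comp$mu_z / (a + mu_i)
  g_beta <- as.numeric(Matrix::crossprod(basis$X, data$y_voxel)) -
    sum(w) * as.numeric(Matrix::crossprod(basis$X, comp$mu_x))
  g_gamma <- if (!is.null(Z) && ncol(Z) > 0)
    as.numeric(crossprod(Z, data$y_study - w * comp$U)) else numeric(0)
  g_a <- M * (log(a) + 1) - M * digamma(a) + sum(digamma(data$y_study + a)) -
    sum(log(a + mu_i) + (data$y_study + a) / (a + mu_i))
  c(g_beta, g_gamma, -a * g_a)  # chain rule: d a / d log(alpha) = -a
}

#' Quasi-Poisson variance function
#'
#' `V(Y) = theta * mu` elementwise; used only to weight IRLS and scale
#' standard errors. `theta < 1` (under-dispersion) is out of scope.
#'
#' @param mu mean vector.
#' @param theta dispersion multiplier, >= 1.
#' @export
quasi_poisson_variance <- function(mu, theta) {
  if (!is.finite(theta) || theta < 1)
    stop("domain error: theta must be >= 1")
  theta * mu
}

#' Family objective on the parameter vector used by the optimizer
#'
#' Parameter layout: `c(beta, gamma, log(alpha))` for NB families,
#' `c(beta, gamma)` for Poisson. Dispersion is optimized on the log scale to
#' enforce positivity without constrained optimization.
#' @keywords internal
family_objective <- function(family, data, basis, Z) {
  P <- basis$P
  R <- if (is.null(Z)) 0L else ncol(Z)
  M <- data$M
  has_alpha <- family %in% c("nb", "clustered_nb")
  ll <- function(par) {
    beta <- par[seq_len(P)]
    gamma <- if (R > 0) par[P + seq_len(R)] else numeric(0)
    comp <- suppressWarnings(intensity(beta, gamma, basis, Z, M = M))
    switch(family,
      poisson = loglik_poisson(data, comp),
      nb = loglik_nb(data, comp, exp(par[P + R + 1L])),
      clustered_nb = loglik_clustered_nb(data, comp, exp(par[P + R + 1L])))
  }
  gr <- function(par) {
    beta <- par[seq_len(P)]
    gamma <- if (R > 0) par[P + seq_len(R)] else numeric(0)
    comp <- suppressWarnings(intensity(beta, gamma, basis, Z, M = M))
    if (family == "poisson") return(grad_poisson(data, comp, basis, Z))
    alpha <- exp(par[P + R + 1L])
    if (family == "clustered_nb")
      return(grad_clustered_nb(data, comp, alpha, basis, Z))
    g <- grad_nb_beta_lalpha(data, comp, alpha, basis)
    g_gamma <- numeric(R)
    if (R > 0) {
      # central finite differences for the covariate block (R is small)
      h <- (.Machine$double.eps)^(1/3) * (1 + abs(gamma))
      for (k in seq_len(R)) {
        pp <- par; pp[P + k] <- pp[P + k] + h[k]
        pm <- par; pm[P + k] <- pm[P + k] - h[k]
        g_gamma[k] <- (ll(pp) - ll(pm)) / (2 * h[k])
      }
    }
    c(g$g_beta, g_gamma, g$g_lalpha)
  }
  list(ll = ll, gr = gr, n_par = P + R + as.integer(has_alpha),
       P = P, R = R, has_alpha = has_alpha)
}

#' Serialize fitted model parameters to JSON
#'
#' @param fit a `cbmr_fit`.
#' @param path optional output file.
#' @export
params_json <- function(fit, path = NULL) {
  s <- list(family = fit$family, beta = fit$beta, gamma = fit$gamma,
            alpha = fit$alpha, theta = fit$theta,
            basis_fingerprint = list(P = fit$basis$P,
                                     spacing_mm = fit$basis$config$spacing_mm,
                                     kept_columns = fit$basis$kept_columns),
            loglik = fit$loglik, converged = fit$converged)
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
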