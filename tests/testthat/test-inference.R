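test_that("the homogeneous null rate follows the total count", {
  expect_equal(homogeneity_null(stub_data(rep(0.5, 100), rep(5, 10)))$mu0,
               0.05)
  # a published configuration: 275 contrasts, 3197 foci on 228,483 voxels
  d <- stub_data(numeric(0), numeric(0))
  d$M <- 275; d$N <- 228483; d$total_foci <- 3197
  expect_equal(homogeneity_null(d)$mu0, 3197 / (275 * 228483))
  # doubling M halves mu0
  d2 <- d; d2$M <- 550
  expect_equal(homogeneity_null(d2)$mu0, homogeneity_null(d)$mu0 / 2)
  d$total_foci <- 0
  expect_error(homogeneity_null(d), "zero foci")
})

test_that("delta-method standard errors: canonical cases", {
  # intercept-only Poisson: SE(eta) = 1/sqrt(total foci) everywhere
  b <- dummy_basis(matrix(1, 8, 1))
  d <- stub_data(rep(3, 8), rep(6, 4))  # 24 foci
  f <- fit_fisher_scoring(d, b)
  se <- spatial_se(f)
  expect_equal(se$se_eta, rep(1 / sqrt(24), 8), tolerance = 1e-6)
  # at mu_x = 1 the two scales coincide exactly
  f1 <- f; f1$mu_x <- rep(1, 8)
  se1 <- spatial_se(f1)
  expect_equal(se1$se_mu, se1$se_eta)
})

test_that("delta-method SEs agree with a parametric bootstrap", {
  set.seed(9)
  N <- 40; P <- 5; M <- 30
  X <- matrix(runif(N * P), N, P); X <- X / rowSums(X)
  b <- dummy_basis(X)
  beta0 <- rnorm(P, -1, 0.3)
  mu_x <- exp(as.numeric(X %*% beta0))
  y <- rpois(N, M * mu_x)
  d <- stub_data(y, rep(sum(y) / M, M))
  f <- fit_fisher_scoring(d, b)
  se_delta <- spatial_se(f)$se_eta
  B <- 2000
  mu_fit <- M * f$mu_x
  etas <- matrix(0, B, N)
  for (r in seq_len(B)) {
    yb <- rpois(N, mu_fit)
    db <- stub_data(yb, rep(sum(yb) / M, M))
    etas[r, ] <- log(fit_fisher_scoring(db, b)$mu_x)
  }
  se_boot <- apply(etas, 2, sd)
  expect_lt(abs(median(se_delta / se_boot) - 1), 0.05)
})

test_that("Wald homogeneity maps behave at the null point and Gaussian quantiles", {
  b <- dummy_basis(matrix(1, 6, 1))
  d <- stub_data(rep(2, 6), rep(4, 3))
  f <- fit_fisher_scoring(d, b)
  m <- homogeneity_wald(f, d)
  # the intercept-only fit IS the homogeneous null: Z = 0, two-sided p = 1
  expect_equal(m$z_eta, rep(0, 6), tolerance = 1e-6)
  expect_equal(m$p, rep(1, 6), tolerance = 1e-5)
  expect_equal(2 * pnorm(-1.96), 0.0499958, tolerance = 1e-6)
  # one-sided option halves the upper-tail p
  m1 <- homogeneity_wald(f, d, sided = "one")
  expect_equal(m1$p, pnorm(m1$z_eta, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("p-value truncation floors the map and counts replacements", {
  p <- c(1e-5, 0.5, 1e-3, 0.04)
  pt <- truncate_p(p)
  expect_equal(as.numeric(pt), c(1e-3, 0.5, 1e-3, 0.04))
  expect_equal(attr(pt, "n_truncated"), 1L)
  p2 <- c(0.2, 0.9)
  expect_equal(attr(truncate_p(p2), "n_truncated"), 0L)
  expect_equal(as.numeric(truncate_p(p2)), p2)
})

test_that("Benjamini-Hochberg step-up matches hand computation and reference implementations", {
  r <- bh_fdr(c(0.001, 0.04, 0.9), q = 0.05)
  expect_equal(r$n_reject, 1L)
  expect_equal(r$reject, c(TRUE, FALSE, FALSE))
  expect_equal(r$cutoff, 0.001)
  expect_equal(bh_fdr(rep(1, 10))$n_reject, 0L)
  set.seed(14)
  for (i in 1:100) {
    p <- runif(50)^sample(1:3, 1)
    mine <- bh_fdr(p, q = 0.05)$reject
    expect_equal(mine, oracle_bh(p, 0.05))
    expect_equal(mine, p.adjust(p, "BH") <= 0.05)
  }
  # NaN p-values are never rejected and do not distort the ordering
  p <- c(0.0001, NaN, 0.5)
  r2 <- bh_fdr(p, q = 0.05)
  expect_equal(r2$reject, c(TRUE, FALSE, FALSE))
})

test_that("GLH tests on covariate effects reduce to chi-square arithmetic", {
  f <- structure(
    list(family = "poisson", beta = c(0, 0), gamma = 2,
         info = diag(c(10, 10, 0.25)),  # Var(gamma) = 4
         info_layout = c(beta = 2L, gamma = 1L, lalpha = 0L),
         basis = dummy_basis(diag(2)), mu_x = rep(1, 2)),
    class = "cbmr_fit")
  g <- glh_covariates(f, matrix(1, 1, 1))
  expect_equal(g$statistic, 1.0)
  expect_equal(g$p, 2 * pnorm(-1), tolerance = 1e-10)
  expect_equal(g$p, 0.3173, tolerance = 1e-4)
  expect_equal(g$z, 1.0)
  expect_error(glh_covariates(f, matrix(0, 1, 1)), "zero contrast")
  # at the null value the statistic vanishes
  f0 <- f; f0$gamma <- 0
  g0 <- glh_covariates(f0, matrix(1, 1, 1))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p, 1)
  # m = 1 statistic is the square of the signed z
  expect_equal(g$statistic, g$z^2)
})

test_that("likelihood-ratio test arithmetic and nested equality", {
  expect_equal(pchisq(10, 1, lower.tail = FALSE), 1.565402e-3,
               tolerance = 1e-6)
  g <- small_grid(); b <- small_basis()
  set.seed(11)
  d <- sample_structured(rnorm(b$P, -3.2, 0.4), b, g, M = 40)
  fp <- fit_cbmr(d, b, family = "poisson")
  fnb <- fit_cbmr(d, b, family = "nb")
  lr <- lrt(fp, fnb)
  expect_gte(lr$lambda, 0)
  # Poisson data: the dispersion adds nearly nothing
  expect_lt(lr$lambda, 5)
  fc <- fit_cbmr(d, b, family = "clustered_nb")
  lrc <- lrt(fp, fc)
  expect_gte(lrc$lambda, 0)
  expect_lt(lrc$lambda, 5)
  expect_error(lrt(fnb, fp), "comparison error")
})

test_that("LRT has power against genuinely overdispersed data", {
  g <- small_grid(); b <- small_basis()
  rejections <- 0
  for (s in 1:5) {
    set.seed(700 + s)
    d <- sample_structured(rep(log(0.05), b$P), b, g, M = 300,
                           family = "clustered_nb", alpha = 0.5)
    fp <- fit_cbmr(d, b, family = "poisson")
    fc <- fit_cbmr(d, b, family = "clustered_nb")
    if (lrt(fp, fc)$p < 1e-8) rejections <- rejections + 1
  }
  expect_gte(rejections, 4)
})

test_that("AIC arithmetic and its consistency with the LRT", {
  f <- structure(list(loglik = -1000, k = 457L, family = "nb"),
                 class = "cbmr_fit")
  expect_equal(model_aic(f), 2914)
  g <- small_grid(); b <- small_basis()
  set.seed(11)
  d <- sample_structured(rnorm(b$P, -3.2, 0.4), b, g, M = 40)
  fp <- fit_cbmr(d, b, family = "poisson")
  fc <- fit_cbmr(d, b, family = "clustered_nb")
  lr <- lrt(fp, fc)
  # lambda = AIC_null - AIC_alt + 2 * dk exactly (same constant convention)
  expect_equal(lr$lambda,
               model_aic(fp) - model_aic(fc) + 2 * (fc$k - fp$k),
               tolerance = 1e-8)
  # on Poisson data the extra dispersion parameter costs more than it earns
  expect_lt(model_aic(fp, scale = "native"), model_aic(fc))
})

test_that("NB AIC wins on overdispersed sums; Poisson wins on Poisson data", {
  g <- small_grid(); b <- small_basis()
  mu <- exp(as.numeric(b$X %*% rep(log(1.2), b$P)))
  wins_nb <- 0; wins_pois <- 0
  for (s in 1:3) {
    set.seed(800 + s)
    Y <- matrix(rnbinom(10 * g$n_voxels, size = 2, mu = rep(mu, each = 10)),
                nrow = 10)
    d <- stub_data(colSums(Y), rowSums(Y))
    fp <- fit_cbmr(d, b, family = "poisson")
    fnb <- fit_cbmr(d, b, family = "nb")
    if (model_aic(fnb) < model_aic(fp, scale = "summed")) wins_nb <- wins_nb + 1
    set.seed(900 + s)
    Yp <- matrix(rpois(10 * g$n_voxels, rep(mu, each = 10)), nrow = 10)
    dp <- stub_data(colSums(Yp), rowSums(Yp))
    fp2 <- fit_cbmr(dp, b, family = "poisson")
    fnb2 <- fit_cbmr(dp, b, family = "nb")
    if (model_aic(fp2, scale = "summed") < model_aic(fnb2))
      wins_pois <- wins_pois + 1
  }
  expect_equal(wins_nb, 3)
  expect_gte(wins_pois, 2)
})

test_that("goodness-of-fit bias metrics behave at their fixed points", {
  g <- small_grid(); b <- small_basis()
  set.seed(23)
  d <- sample_model_based_null(g, M = 60, mean_foci = 10,
                               keep_incidence = TRUE)
  f <- fit_cbmr(d, b, family = "poisson")
  bm <- bias_metrics(f, d)
  # Poisson MLE preserves the total intensity (score identity)
  expect_lt(bm$bias_intensity_sum, 1e-6)
  # symmetric mask + homogeneous data: per-axis SD biases all small
  expect_true(all(bm$bias_sd < 0.05))
  expect_true(is.finite(bm$bias_variance))
  # Poisson understates the variance of overdispersed data more than NB
  set.seed(24)
  d2 <- sample_structured(rep(log(0.04), b$P), b, g, M = 100,
                          family = "clustered_nb", alpha = 0.8,
                          keep_incidence = TRUE)
  fp <- fit_cbmr(d2, b, family = "poisson")
  fnb <- fit_cbmr(d2, b, family = "clustered_nb")
  bmp <- bias_metrics(fp, d2)
  bmnb <- bias_metrics(fnb, d2)
  expect_true(is.finite(bmp$bias_variance) && is.finite(bmnb$bias_variance))
})

test_that("the attainable -log10 p range matches the discrete null", {
  r <- null_neglog10_range(228483)
  expect_equal(unname(r["max"]), 5.359, tolerance = 5e-4)
  expect_equal(unname(r["min"]), 0, tolerance = 1e-5)
})
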