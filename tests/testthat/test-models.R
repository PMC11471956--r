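test_that("intensity components follow the factorized linear predictor", {
  inst <- random_instance(N = 6, M = 3, P = 4, R = 2, seed = 7)
  # zero coefficients give unit intensity everywhere
  c0 <- intensity(rep(0, 4), rep(0, 2), inst$basis, inst$Z)
  expect_equal(c0$mu_x, rep(1, 6))
  expect_equal(c0$mu_z, rep(1, 3))
  # a constant added to all spline coefficients multiplies mu_x by e^c
  c1 <- intensity(inst$beta, inst$gamma, inst$basis, inst$Z)
  c2 <- intensity(inst$beta + 0.7, inst$gamma, inst$basis, inst$Z)
  expect_equal(c2$mu_x, exp(0.7) * c1$mu_x, tolerance = 1e-12)
  # mu_ij from components equals the dense per-(study,voxel) rate
  mu_dense <- oracle_dense_mu(inst$beta, inst$gamma, inst$X, inst$Z)
  expect_equal(outer(c1$mu_z, c1$mu_x), mu_dense, tolerance = 1e-12)
  expect_error(intensity(c(NA, 1, 1, 1), inst$gamma, inst$basis, inst$Z),
               "non-finite")
})

test_that("factorized objectives equal dense per-(study,voxel) objectives", {
  for (seed in 1:8) {
    N <- sample(2:8, 1); M <- sample(2:8, 1)
    inst <- random_instance(N = N, M = M, P = min(3, N), R = 2, seed = seed)
    comp <- intensity(inst$beta, inst$gamma, inst$basis, inst$Z)
    mu <- oracle_dense_mu(inst$beta, inst$gamma, inst$X, inst$Z)
    expect_equal(loglik_poisson(inst$data, comp),
                 oracle_dense_poisson_ll(inst$Y, mu), tolerance = 1e-10)
    expect_equal(loglik_clustered_nb(inst$data, comp, 0.6),
                 oracle_dense_clustered_ll(inst$Y, mu, 0.6),
                 tolerance = 1e-10)
  }
})

test_that("tiny Poisson plug-in value and stationarity at the optimum", {
  # N=1, M=2, mu_x=1, mu_z=(1,1), Y_voxel=2, Y_study=(1,1):
  # l = 2*log 1 + 0 - 1*2 = -2
  d <- stub_data(2, c(1, 1))
  comp <- intensity(0, numeric(0), dummy_basis(matrix(1, 1, 1)), NULL, M = 2)
  expect_equal(loglik_poisson(d, comp), -2)
  # scaling the study effect away from the optimum decreases the objective
  inst <- random_instance(N = 10, M = 4, P = 3, R = 0, seed = 3)
  f <- fit_fisher_scoring(
    stub_data(inst$data$y_voxel, inst$data$y_study), inst$basis)
  comp_hat <- intensity(f$beta, numeric(0), inst$basis, NULL, M = 4)
  comp_2x <- comp_hat; comp_2x$mu_z <- 2 * comp_hat$mu_z
  comp_2x$s1 <- 2 * comp_hat$s1
  expect_lt(loglik_poisson(inst$data, comp_2x),
            loglik_poisson(inst$data, comp_hat))
})

test_that("NB moment matching reproduces the exact convolution moments", {
  # no covariates: alpha' = alpha/M, r = M/alpha
  b1 <- dummy_basis(matrix(1, 1, 1))
  comp <- intensity(log(0.1), numeric(0), b1, NULL, M = 10)
  mm <- nb_moment_match(comp, alpha = 0.5)
  expect_equal(mm$alpha_prime, 0.05)
  expect_equal(mm$r, 20)
  expect_equal(mm$p, 0.1 / 2.1)
  # matched mean equals the summed intensity
  expect_equal(mm$r * mm$p / (1 - mm$p), 1, tolerance = 1e-12)

  # random study effects: matched mean/variance equal the exact first two
  # moments of the convolution of M independent NB variates
  set.seed(21)
  Z <- scale(matrix(rnorm(6), 6, 1), scale = FALSE)
  comp2 <- intensity(log(0.3), 0.4, b1, Z)
  alpha <- 0.7
  mm2 <- nb_moment_match(comp2, alpha)
  mu_i <- comp2$mu_x[1] * comp2$mu_z
  exact_mean <- sum(mu_i)
  exact_var <- sum(mu_i + alpha * mu_i^2)
  expect_equal(mm2$r * mm2$p[1] / (1 - mm2$p[1]), exact_mean,
               tolerance = 1e-12)
  expect_equal(mm2$r * mm2$p[1] / (1 - mm2$p[1])^2, exact_var,
               tolerance = 1e-12)
  expect_error(nb_moment_match(comp2, 0), "domain error")
})

test_that("NB objective is exact for a single study and near the convolution for several", {
  # M = 1: no convolution, the NB pmf is exact
  b2 <- dummy_basis(diag(2))
  d1 <- stub_data(c(2, 0), 2)
  comp <- intensity(log(c(0.8, 0.3)), numeric(0), b2, NULL, M = 1)
  alpha <- 0.4
  expect_equal(loglik_nb(d1, comp, alpha),
               sum(dnbinom(c(2, 0), size = 1 / alpha,
                           mu = c(0.8, 0.3), log = TRUE)),
               tolerance = 1e-10)

  # M = 3 identical studies, one voxel: matched size r = s1^2/(alpha s2) = 15
  b1 <- dummy_basis(matrix(1, 1, 1))
  d3 <- stub_data(4, c(2, 1, 1))
  comp3 <- intensity(log(2), numeric(0), b1, NULL, M = 3)
  mm <- nb_moment_match(comp3, 0.2)
  expect_equal(mm$r, 15)
  expect_equal(loglik_nb(d3, comp3, 0.2),
               dnbinom(4, size = mm$r, prob = 1 - mm$p, log = TRUE),
               tolerance = 1e-10)
  # the matched moments equal those of the 3-fold convolution (exact),
  # and the pmf approximation error at the observed count is small
  conv <- stats::convolve(dnbinom(0:60, size = 5, mu = 2),
                          rev(dnbinom(0:60, size = 5, mu = 2)), type = "open")
  conv <- stats::convolve(conv[1:61], rev(dnbinom(0:60, size = 5, mu = 2)),
                          type = "open")[1:61]
  m_conv <- sum((0:60) * conv)
  v_conv <- sum((0:60)^2 * conv) - m_conv^2
  expect_equal(mm$r * mm$p / (1 - mm$p), m_conv, tolerance = 1e-6)
  expect_equal(mm$r * mm$p / (1 - mm$p)^2, v_conv, tolerance = 1e-4)
  expect_lt(abs(exp(loglik_nb(d3, comp3, 0.2)) - conv[5]) / conv[5], 0.02)
})

test_that("NB and clustered NB collapse to Poisson as alpha tends to zero", {
  inst <- random_instance(N = 7, M = 4, P = 3, R = 2, seed = 11)
  comp <- intensity(inst$beta, inst$gamma, inst$basis, inst$Z)
  l_pois <- loglik_poisson(inst$data, comp)
  # clustered NB shares the per-observation scale with Poisson exactly
  expect_equal(loglik_clustered_nb(inst$data, comp, 1e-9), l_pois,
               tolerance = 1e-6)
  # the NB objective lives on the per-voxel-sum scale: the limit offset is
  # sum lgamma(Y_voxel+1) + sum_i Y_i log mu_z_i - total * log(sum mu_z)
  offset <- sum(lgamma(inst$data$y_voxel + 1)) +
    sum(inst$data$y_study * log(comp$mu_z)) -
    inst$data$total_foci * log(comp$s1)
  expect_equal(loglik_nb(inst$data, comp, 1e-9), l_pois - offset,
               tolerance = 1e-5)
})

test_that("clustered NB matches Poisson-Gamma quadrature and its covariance law", {
  # single study, two voxels, alpha = 1: exact hierarchical probability
  b2 <- dummy_basis(diag(2))
  d <- stub_data(c(1, 0), 1)
  comp <- intensity(log(c(0.5, 0.5)), numeric(0), b2, NULL, M = 1)
  expect_equal(loglik_clustered_nb(d, comp, 1),
               oracle_clustered_quadrature_ll(c(1, 0), c(0.5, 0.5), 1),
               tolerance = 1e-9)
  # within-study covariance alpha * mu_j * mu_j' by direct simulation of
  # the generative hierarchy (no clamping)
  set.seed(31)
  M <- 50000; alpha <- 0.8; mu <- c(0.4, 0.7)
  lam <- rgamma(M, shape = 1 / alpha, rate = 1 / alpha)
  y1 <- rpois(M, lam * mu[1]); y2 <- rpois(M, lam * mu[2])
  expect_equal(cov(y1, y2), alpha * mu[1] * mu[2], tolerance = 0.1)
  expect_equal(mean(y1), mu[1], tolerance = 0.05)
  expect_equal(var(y1), mu[1] + alpha * mu[1]^2, tolerance = 0.05)
})

test_that("quasi-Poisson variance function scales the mean", {
  expect_equal(quasi_poisson_variance(c(0.3, 2), 1), c(0.3, 2))
  expect_equal(quasi_poisson_variance(0.3, 2), 0.6)
  expect_error(quasi_poisson_variance(0.3, 0.5), "domain error")
})

test_that("analytic scores match numerical differentiation for every family", {
  inst <- random_instance(N = 8, M = 5, P = 4, R = 2, seed = 13)
  for (family in c("poisson", "nb", "clustered_nb")) {
    obj <- cbmr:::family_objective(family, inst$data, inst$basis, inst$Z)
    par <- c(inst$beta, inst$gamma,
             if (obj$has_alpha) log(0.4))
    num <- vapply(seq_along(par), function(k) {
      h <- 1e-6
      pp <- par; pp[k] <- pp[k] + h
      pm <- par; pm[k] <- pm[k] - h
      (obj$ll(pp) - obj$ll(pm)) / (2 * h)
    }, numeric(1))
    expect_equal(obj$gr(par), num, tolerance = 1e-5)
  }
})
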