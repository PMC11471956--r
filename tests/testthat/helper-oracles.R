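# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (dense per-(study,voxel) objectives,
# textbook recursions, quadrature) and never call the package code paths
# they are used to check.

# dense M x N intensity matrix from the model's linear predictor
oracle_dense_mu <- function(beta, gamma, X, Z) {
  eta_x <- as.numeric(as.matrix(X) %*% beta)
  eta_z <- if (length(gamma) > 0) as.numeric(Z %*% gamma) else numeric(nrow(Z))
  exp(outer(eta_z, eta_x, `+`))
}

# full per-(study,voxel) Poisson log-likelihood of a 0/1 count matrix
# (log Y! terms vanish for counts <= 1)
oracle_dense_poisson_ll <- function(Y, mu) sum(Y * log(mu) - mu)

# full clustered-NB log-likelihood of a count matrix, summed per study
oracle_dense_clustered_ll <- function(Y, mu, alpha) {
  a <- 1 / alpha
  M <- nrow(Y)
  yi <- rowSums(Y)
  M * a * log(a) - M * lgamma(a) + sum(lgamma(yi + a)) -
    sum(lgamma(Y + 1)) -
    sum((yi + a) * log(rowSums(mu) + a)) + sum(Y * log(mu))
}

# clustered-NB probability of one study's count vector by numerical
# integration over the study-level Gamma latent effect
oracle_clustered_quadrature_ll <- function(y, mu, alpha) {
  f <- function(l) stats::dgamma(l, shape = 1 / alpha, rate = 1 / alpha) *
    vapply(l, function(li) prod(stats::dpois(y, li * mu)), numeric(1))
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value)
}

# textbook Cox-de Boor recursion for one B-spline basis function
oracle_coxdeboor <- function(x, knots, i, d) {
  if (d == 0) return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  left <- 0
  if (knots[i + d] > knots[i])
    left <- (x - knots[i]) / (knots[i + d] - knots[i]) *
      oracle_coxdeboor(x, knots, i, d - 1)
  right <- 0
  if (knots[i + d + 1] > knots[i + 1])
    right <- (knots[i + d + 1] - x) / (knots[i + d + 1] - knots[i + 1]) *
      oracle_coxdeboor(x, knots, i + 1, d - 1)
  left + right
}

oracle_bspline_matrix <- function(x, knots, degree) {
  n <- length(knots) - degree - 1
  vapply(seq_len(n), function(i) oracle_coxdeboor(x, knots, i, degree),
         numeric(length(x)))
}

# explicit triple-loop tensor product, row order x index fastest
oracle_tensor <- function(Cx, Cy, Cz) {
  vx <- nrow(Cx); vy <- nrow(Cy); vz <- nrow(Cz)
  nx <- ncol(Cx); ny <- ncol(Cy); nz <- ncol(Cz)
  C <- matrix(0, vx * vy * vz, nx * ny * nz)
  for (k in 1:vz) for (j in 1:vy) for (i in 1:vx) {
    row <- i + vx * ((j - 1) + vy * (k - 1))
    for (c in 1:nz) for (b in 1:ny) for (a in 1:nx) {
      col <- a + nx * ((b - 1) + ny * (c - 1))
      C[row, col] <- Cx[i, a] * Cy[j, b] * Cz[k, c]
    }
  }
  C
}

# step-up BH by direct enumeration of every threshold
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k_ok <- 0
  for (k in seq_len(m)) if (p[ord[k]] <= q * k / m) k_ok <- k
  rej <- rep(FALSE, m)
  if (k_ok > 0) rej[ord[seq_len(k_ok)]] <- TRUE
  rej
}
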