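# Shared 2-band worked example (hand-derived):
# Px = [[1, .5], [.5, 1]], Gxy = [.3, .2]
Px2 <- matrix(c(1, 0.5, 0.5, 1), 2)
Gxy2 <- c(0.3, 0.2)

test_that("phenotypic covariance matches element-wise oracles", {
  set.seed(30)
  n <- 40
  M <- scale(matrix(rnorm(n * 3), n, 3), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))    # orthonormal, mean-zero columns
  X <- Q * sqrt(n - 1)
  expect_equal(phen_cov(X), diag(3), tolerance = 1e-10)

  X2 <- cbind(a = rnorm(30), b = rnorm(30))
  X2 <- cbind(X2, c = X2[, 2])
  P <- phen_cov(X2)
  expect_equal(P[2, 2], P[3, 3], tolerance = 1e-12)
  expect_equal(P[2, 3], P[2, 2], tolerance = 1e-12)

  X3 <- matrix(rnorm(500), 100, 5)
  expect_equal(unname(phen_cov(X3)), two_pass_cov(X3), tolerance = 1e-12)
  expect_identical(phen_cov(X3), t(phen_cov(X3)))
  expect_error(phen_cov(X3[1, , drop = FALSE]), "at least 2")
})

test_that("standard index solves the normal equations", {
  expect_equal(coef(standard_si(diag(3), c(1, -2, 0.5))), c(1, -2, 0.5))
  expect_equal(coef(standard_si(Px2, Gxy2)), c(0.2667, 0.0667),
               tolerance = 1e-3)
  expect_equal(coef(standard_si(Px2, c(0, 0))), c(0, 0))
  Psing <- matrix(1, 3, 3) + diag(1e-15, 3)
  expect_error(standard_si(Psing, c(1, 1, 1)), "regularized")
})

test_that("ridge index shrinks correctly and reduces to the standard index", {
  expect_equal(coef(l2_psi(Px2, Gxy2, 0.5)), c(0.175, 0.075), tolerance = 1e-6)
  expect_equal(coef(l2_psi(Px2, Gxy2, 0)), coef(standard_si(Px2, Gxy2)),
               tolerance = 1e-10)
  b_big <- coef(l2_psi(Px2, Gxy2, 1e6))
  expect_lt(max(abs(b_big)), 1e-5 * max(abs(Gxy2)))
  expect_error(l2_psi(Px2, Gxy2, -0.1), "non-negative")

  # monotone shrinkage of the L2 norm along a 50-point grid
  set.seed(31)
  A <- matrix(rnorm(100), 20, 5)
  P <- crossprod(A) / 19
  G <- rnorm(5, 0, 0.3)
  norms <- sapply(exp(seq(log(1e-4), log(10), length.out = 50)),
                  function(l) sqrt(sum(coef(l2_psi(P, G, l))^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("coordinate descent satisfies the hand-derived L1 example and KKT", {
  pth <- en_psi(Px2, Gxy2, lambda = c(0.3, 0.2, 0.1), alpha = 1)
  expect_equal(unname(pth$beta[, 1]), c(0, 0))       # lambda >= max|G|
  expect_equal(unname(pth$beta[, 2]), c(0.1, 0), tolerance = 1e-6)
  for (k in 1:3)
    expect_lt(kkt_violation(Px2, Gxy2, pth$beta[, k], pth$lambda[k], 1), 1e-6)

  # alpha = 0 reduction to the ridge solution
  set.seed(32)
  A <- matrix(rnorm(300), 30, 10)
  P <- crossprod(A) / 29
  G <- rnorm(10, 0, 0.2)
  lam <- si_lambda_grid(G, alpha = 0, nlambda = 12, min_ratio = 1e-3)
  p0 <- en_psi(P, G, lambda = lam, alpha = 0)
  for (k in seq_along(lam))
    expect_equal(unname(p0$beta[, k]), coef(l2_psi(P, G, lam[k])),
                 tolerance = 1e-8)

  expect_error(en_psi(P, G, lambda = c(0.1, 0.2), alpha = 1), "decreasing")
  expect_error(en_psi(P, G, alpha = 1.4), "alpha")
})

test_that("warm and cold starts of coordinate descent agree", {
  set.seed(33)
  A <- matrix(rnorm(60 * 15), 60, 15)
  P <- crossprod(A) / 59
  G <- rnorm(15, 0, 0.25)
  lam <- si_lambda_grid(G, alpha = 1, nlambda = 20, min_ratio = 1e-3)
  warm <- en_psi(P, G, lambda = lam, alpha = 1)
  for (k in seq_along(lam)) {
    cold <- en_psi(P, G, lambda = lam[k], alpha = 1)
    expect_lt(max(abs(warm$beta[, k] - cold$beta[, 1])), 1e-6)
  }
})

test_that("LARS path has the hand-derived knots and matches oracles", {
  lp <- lars_psi(Px2, Gxy2)
  expect_equal(lp$lambda[1:2], c(0.3, 0.1), tolerance = 1e-8)
  expect_equal(coef(lp, 0.2), matrix(c(0.1, 0)), tolerance = 1e-8)
  expect_equal(unname(lp$beta[, ncol(lp$beta)]),
               coef(standard_si(Px2, Gxy2)), tolerance = 1e-8)

  # a null genetic covariance gives the single zero solution
  lp0 <- lars_psi(Px2, c(0, 0))
  expect_identical(ncol(lp0$beta), 1L)
  expect_true(all(lp0$beta == 0))

  # the whole set of zero solutions is exactly [lambda_max, Inf)
  expect_true(all(coef(lp, max(abs(Gxy2))) == 0))
  expect_true(all(coef(lp, 10) == 0))
  expect_true(any(coef(lp, max(abs(Gxy2)) * 0.999) != 0))

  # random p = 10 instance against the brute-force enumeration oracle
  # (evaluated at p = 5 sub-blocks for tractability) and against CD
  set.seed(34)
  A <- matrix(rnorm(50 * 10), 50, 10)
  P <- crossprod(A) / 49
  G <- rnorm(10, 0, 0.3)
  lp10 <- lars_psi(P, G)
  lams <- exp(seq(log(max(abs(G)) * 0.95), log(max(abs(G)) * 1e-3),
                  length.out = 20))
  bl <- coef(lp10, lams)
  bc <- en_psi(P, G, lambda = lams, alpha = 1, tol = 1e-12)$beta
  expect_lt(max(abs(bl - bc)), 1e-5)
  for (k in seq_along(lams))
    expect_lt(kkt_violation(P, G, bl[, k], lams[k], 1), 1e-8)

  # exact brute-force QP oracle at p = 5
  set.seed(35)
  A5 <- matrix(rnorm(40 * 5), 40, 5)
  P5 <- crossprod(A5) / 39
  G5 <- rnorm(5, 0, 0.3)
  lp5 <- lars_psi(P5, G5)
  for (l in exp(seq(log(max(abs(G5)) * 0.9), log(1e-3), length.out = 10))) {
    expect_equal(unname(coef(lp5, l)[, 1]), enet_qp_oracle(P5, G5, l, 1),
                 tolerance = 1e-5)
  }

  # exact ties enter lowest-band-first and are counted
  lpt <- lars_psi(diag(3), c(0.3, 0.3, 0.1))
  expect_gte(attr(lpt, "ties"), 1L)
  expect_equal(unname(coef(lpt, 0.2)[, 1]), c(0.1, 0.1, 0), tolerance = 1e-10)
})

test_that("KKT certificates hold at LARS knots of correlated instances", {
  set.seed(36)
  for (rep in 1:5) {
    Z <- matrix(rnorm(80 * 12), 80, 12) %*% diag(runif(12, 0.5, 2))
    Z[, 2] <- Z[, 1] + rnorm(80, 0, 0.1)   # strong collinearity
    P <- crossprod(scale(Z)) / 79
    G <- rnorm(12, 0, 0.2)
    lp <- lars_psi(P, G)
    for (k in seq_along(lp$lambda)) {
      if (lp$lambda[k] <= 1e-10) next
      expect_lt(kkt_violation(P, G, lp$beta[, k], lp$lambda[k], 1), 1e-8)
    }
  }
})

test_that("PC index reduces to the standard index and matches score solves", {
  set.seed(37)
  X <- matrix(rnorm(60 * 5), 60, 5)
  dec <- spectral(X)
  G <- rnorm(5, 0, 0.3)
  G_wy <- rotate_gencov(dec, G)
  b_full <- coef(pc_si(dec, G_wy, q = 5))
  b_std <- coef(standard_si(phen_cov(X), G))
  expect_equal(b_full, b_std, tolerance = 1e-8)

  # q = 1: coefficients proportional to the leading right-singular vector
  b1 <- coef(pc_si(dec, G_wy, q = 1))
  expect_equal(b1, as.numeric(dec$v[, 1]) * (60 - 1) * G_wy[1] / dec$d[1]^2,
               tolerance = 1e-12)

  # exact rank-3 matrix: index values equal the score-space regression
  L <- matrix(rnorm(15), 5, 3)
  S <- matrix(rnorm(90 * 3), 90, 3)
  X3 <- S %*% t(L)
  dec3 <- spectral(X3)
  G3_wy <- c(0.2, -0.1, 0.05)
  b3 <- coef(pc_si(dec3, G3_wy, q = 3))
  W3 <- pc_scores(dec3, 3)
  gamma_oracle <- (90 - 1) * G3_wy / dec3$d[1:3]^2
  Xc <- sweep(X3, 2, colMeans(X3))
  expect_equal(as.numeric(Xc %*% b3), as.numeric(W3 %*% gamma_oracle),
               tolerance = 1e-8)
  expect_error(pc_si(dec3, c(G3_wy, 0), q = 4), "rank = 3")

  # SVD reconstruction sanity on the decomposition object
  expect_equal(crossprod(dec3$u[, 1:3]), diag(3), tolerance = 1e-8)
  expect_lt(max(abs(Xc - dec3$u %*% diag(dec3$d) %*% t(dec3$v))), 1e-6)
})

test_that("index evaluation is an exact matrix-vector product with label checks", {
  set.seed(38)
  X <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("b", 1:4)))
  expect_identical(compute_index(X, rep(0, 4)), rep(0, 20))
  expect_equal(compute_index(X, c(0, 1, 0, 0)), as.numeric(X[, 2]))
  beta <- rnorm(4)
  oracle <- vapply(seq_len(20), function(i) sum(X[i, ] * beta), numeric(1))
  expect_equal(compute_index(X, beta), oracle, tolerance = 1e-12)

  si <- standard_si(phen_cov(X), c(b1 = .1, b2 = 0, b3 = .2, b4 = 0))
  Xbad <- X
  colnames(Xbad) <- c("b1", "b9", "b3", "b4")
  expect_error(compute_index(Xbad, si), "b9")
  expect_error(compute_index(X[, 1:3], si), "coefficients")
})

test_that("the psi() front end dispatches and its methods work", {
  set.seed(39)
  X <- matrix(rnorm(50 * 6), 50, 6)
  P <- phen_cov(X)
  G <- rnorm(6, 0, 0.2)
  expect_s3_class(psi(P, G, method = "standard"), "psi")
  expect_s3_class(psi(P, G, method = "L2", lambda = 0.1), "psi")
  pthL1 <- psi(P, G, method = "L1")
  expect_s3_class(pthL1, "psi_path")
  expect_s3_class(psi(P, G, method = "EN", alpha = 0.5), "psi_path")
  dec <- spectral(X)
  fitpc <- psi(Gxy = G, method = "PC", decomp = dec, q = 3)
  expect_s3_class(fitpc, "psi")
  expect_identical(fitpc$q, 3L)

  fit <- psi(P, G, method = "standard")
  expect_equal(predict(fit, X), as.numeric(X %*% coef(fit)))
  expect_output(print(fit), "standard")
  expect_output(print(pthL1), "penalties")
  expect_output(summary(fit), "active")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(pthL1))
})
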