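test_that("trial-blocked partitions count, reproduce and sample uniformly", {
  trials <- paste0("T", 1:39)
  parts <- make_partitions(trials, n_train_trials = 26, n_partitions = 25,
                           seed = 40)
  for (p in parts) {
    expect_length(p$train, 26)
    expect_length(p$test, 13)
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), trials)
  }
  parts2 <- make_partitions(trials, n_train_trials = 26, n_partitions = 25,
                            seed = 40)
  expect_identical(parts, parts2)

  # long-run frequency of each trial in the testing sets is 13/39
  manyp <- make_partitions(trials, n_train_trials = 26, n_partitions = 1000,
                           seed = 41)
  freq <- table(unlist(lapply(manyp, `[[`, "test"))) / 1000
  expect_true(all(abs(freq - 13 / 39) < 0.05))

  expect_error(make_partitions(trials, n_train_trials = 39), "n_train_trials")
  expect_error(make_partitions(trials, n_train_trials = 0), "n_train_trials")
})

test_that("accuracy decomposition and self-index identities hold exactly", {
  d <- balanced_oneway(q = 150, r = 3, s2g = 0.6, s2e = 0.4, seed = 42)
  set.seed(43)
  idx <- 0.7 * d$y + rnorm(length(d$y), 0, 0.5)
  ev <- evaluate_index(idx, d$y, d$g)
  expect_false(ev$undefined)
  expect_equal(ev$acc, sqrt(ev$h2_I) * ev$r_g, tolerance = 1e-10)
  expect_equal(ev$re, sqrt(ev$h2_I / ev$h2_y) * ev$r_g, tolerance = 1e-10)

  # the target used as its own index: r_g = 1, Acc = h_y, RE = 1
  evs <- evaluate_index(d$y, d$y, d$g)
  expect_equal(evs$r_g, 1, tolerance = 1e-8)
  expect_equal(evs$acc, sqrt(evs$h2_y), tolerance = 1e-8)
  expect_equal(evs$re, 1, tolerance = 1e-8)

  # an index carrying no genetic signal (pure within-genotype contrast,
  # all genotype means identical) is flagged, not NaN-propagated
  idx0 <- rep(c(-1, 0, 1), times = 150)
  ev0 <- evaluate_index(idx0, d$y, d$g)
  expect_true(ev0$undefined)
  expect_true(is.na(ev0$acc))
})

test_that("partition summaries give the right moments and CI coverage", {
  s <- summarize_partitions(c(0.4, 0.6))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0.1414, tolerance = 1e-3)

  s0 <- summarize_partitions(rep(0.37, 6))
  expect_equal(s0$sd, 0)
  expect_equal(s0$ci_lower, s0$ci_upper)

  # coverage of the 95% CI for a known mean
  set.seed(45)
  cover <- mean(replicate(400, {
    v <- rnorm(100, mean = 0.5, sd = 0.1)
    s <- summarize_partitions(v)
    s$ci_lower <= 0.5 && 0.5 <= s$ci_upper
  }))
  expect_gt(cover, 0.90)
  expect_lt(cover, 0.99)

  expect_error(summarize_partitions(0.4), "at least 2")
})

test_that("vegetation indices follow the NDVI formulas and window rules", {
  wl <- c(545, 555, 665, 675, 800, 840)
  X <- rbind(c(0.2, 0.2, 0.1, 0.1, 0.5, 0.5),
             c(0.3, 0.3, 0.2, 0.2, 0.3, 0.3))
  rndvi <- vegetation_index(X, wl, kind = "RNDVI")
  expect_equal(rndvi[1], (0.5 - 0.1) / (0.5 + 0.1), tolerance = 1e-12)
  gndvi <- vegetation_index(X, wl, kind = "GNDVI")
  expect_equal(gndvi[2], 0, tolerance = 1e-12)  # NIR == Green
  expect_true(all(abs(c(rndvi, gndvi)) <= 1))

  expect_error(vegetation_index(X[, 1:4], wl[1:4], kind = "RNDVI"), "nir")
  X0 <- X
  X0[1, ] <- 0
  expect_error(vegetation_index(X0, wl, kind = "RNDVI"), "zero")
})

test_that("phenotypic-prediction baseline recovers planted sparse signals", {
  set.seed(46)
  n <- 150
  X <- matrix(rnorm(n * 12), n, 12)
  y <- 2 * X[, 1] - 1.5 * X[, 5] + 0.5 * X[, 8] + rnorm(n, 0, 0.3)
  pth <- l1_phen(X, y)
  hit <- apply(pth$beta != 0, 2, function(a)
    all(which(a) %in% c(1, 5, 8)) && sum(a) == 3)
  expect_true(any(hit))

  # y orthogonal to every band: the path is identically zero
  yo <- rnorm(n)
  Xc <- sweep(X, 2, colMeans(X))
  yo <- yo - Xc %*% solve(crossprod(Xc), crossprod(Xc, yo))
  ptho <- l1_phen(X, as.numeric(yo), lambda = c(1e-3, 1e-5))
  expect_true(all(abs(ptho$beta) < 1e-10))

  # p = 5 instance against the brute-force oracle
  set.seed(47)
  X5 <- matrix(rnorm(60 * 5), 60, 5)
  y5 <- X5[, 2] - 0.5 * X5[, 4] + rnorm(60, 0, 0.5)
  X5c <- sweep(X5, 2, colMeans(X5))
  P5 <- phen_cov(X5)
  G5 <- as.numeric(crossprod(X5c, y5 - mean(y5))) / 59
  lam <- si_lambda_grid(G5, 1, nlambda = 8, min_ratio = 1e-2)
  pth5 <- l1_phen(X5, y5, lambda = lam)
  for (k in seq_along(lam))
    expect_equal(unname(pth5$beta[, k]), enet_qp_oracle(P5, G5, lam[k], 1),
                 tolerance = 1e-5)
})

test_that("tuning degenerates to the standard index on a single grid point", {
  truth <- sim_truth(p = 6, n_factors = 3, decay = 0.1, h2_bands = 0.6,
                     h2_target = 0.5,
                     r_g_profile = c(0.5, 0.4, 0.3, 0, 0, 0))
  dat <- adjusted_sim(truth, n_trials = 15, genotypes_per_trial = 10,
                      replicates = 3, seed = 48)
  parts <- make_partitions(dat$trial, n_partitions = 4, seed = 49)
  tn <- tune_si(dat$y, dat$X, dat$genotype, dat$trial, method = "L2",
                partitions = parts, lambda = c(1e-8))
  # manual re-computation: at lambda ~ 0 the L2 index is the standard index
  accs <- sapply(parts, function(pt) {
    tr <- dat$trial %in% pt$train
    sc <- list(center = colMeans(dat$X[tr, ]),
               scale = apply(dat$X[tr, ], 2, sd))
    Xtr <- sweep(sweep(dat$X[tr, ], 2, sc$center), 2, sc$scale, "/")
    Xte <- sweep(sweep(dat$X[!tr, ], 2, sc$center), 2, sc$scale, "/")
    G <- gen_covariance_panel(dat$y[tr] / sd(dat$y[tr]), Xtr,
                              dat$genotype[tr])$G
    b <- coef(standard_si(phen_cov(Xtr), G))
    evaluate_index(as.numeric(Xte %*% b), dat$y[!tr], dat$genotype[!tr])$acc
  })
  expect_equal(unname(tn$curve$mean_acc), mean(accs), tolerance = 1e-6)
})

test_that("PC tuning finds the generating rank of noise-free bands", {
  # bands are exactly rank 3 (pure genetic signal, no band noise or nuisance)
  truth <- sim_truth(p = 8, n_factors = 3, decay = 0.25, h2_bands = 1,
                     h2_target = 0.4,
                     r_g_profile = c(0.5, 0.5, 0.4, 0.3, 0.2, 0.1, 0.1, 0.1),
                     nuisance = c(trial = 0, rep = 0, subblock = 0))
  dat <- adjusted_sim(truth, n_trials = 16, genotypes_per_trial = 12,
                      replicates = 3, seed = 50)
  parts <- make_partitions(dat$trial, n_partitions = 4, seed = 51)
  tn <- tune_si(dat$y, dat$X, dat$genotype, dat$trial, method = "PC",
                partitions = parts, q_grid = 1:6)
  # ranks above 3 are unreachable; accuracy must peak at the true rank
  expect_true(all(is.na(tn$curve$mean_acc[4:6]) |
                    is.nan(tn$curve$mean_acc[4:6])))
  expect_identical(tn$best$q, 3L)
})

test_that("index coefficients never depend on testing-set plots", {
  truth <- sim_truth(p = 10, n_factors = 4, decay = 0.1, h2_bands = 0.5,
                     h2_target = 0.5,
                     r_g_profile = c(rep(0.4, 4), rep(0, 6)))
  dat <- adjusted_sim(truth, n_trials = 12, genotypes_per_trial = 10,
                      replicates = 2, seed = 52)
  parts <- make_partitions(dat$trial, n_partitions = 2, seed = 53)
  lam <- c(0.2, 0.1, 0.05)
  tn1 <- tune_si(dat$y, dat$X, dat$genotype, dat$trial, method = "L1",
                 partitions = parts, lambda = lam, keep_coefs = TRUE)
  # corrupt every testing-set record of partition 1 (labels untouched)
  te <- dat$trial %in% parts[[1]]$test
  y2 <- dat$y
  X2 <- dat$X
  y2[te] <- y2[te] * 3 + 7
  X2[te, ] <- X2[te, ] * -2 + 1
  tn2 <- tune_si(y2, X2, dat$genotype, dat$trial, method = "L1",
                 partitions = parts[1], lambda = lam, keep_coefs = TRUE)
  expect_equal(tn1$part_coefs[[1]], tn2$part_coefs[[1]], tolerance = 1e-12)
})

test_that("tuned regularization beats the plug-in standard index when p >> signal", {
  # directional check at desk scale; the full-size version runs in the
  # acceptance suite
  set.seed(54)
  truth <- sim_truth(p = 60, n_factors = 5, decay = 0.07, h2_bands = 0.5,
                     h2_target = 0.5,
                     r_g_profile = 0.45 * exp(-((1:60 - 15) / 12)^2))
  wins <- replicate(5, {
    dat <- adjusted_sim(truth, n_trials = 20, genotypes_per_trial = 10,
                        replicates = 2, seed = sample.int(1e6, 1))
    parts <- make_partitions(dat$trial, n_train_trials = 13,
                             n_partitions = 2, seed = sample.int(1e6, 1))
    tn <- tune_si(dat$y, dat$X, dat$genotype, dat$trial, method = "L1",
                  partitions = parts)
    Xs <- scale(dat$X)
    G <- gen_covariance_panel(dat$y / sd(dat$y), Xs, dat$genotype)$G
    bstd <- standard_si(phen_cov(Xs), G)
    true_accuracy(tn$optimal, truth) > true_accuracy(bstd, truth)
  })
  expect_gte(mean(wins), 0.8)
})
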