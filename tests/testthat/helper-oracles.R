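# Independent oracles and small fixture builders used across the suite.

# balanced one-way layout: q genotypes x r replicates
balanced_oneway <- function(q, r, s2g, s2e, seed) {
  withr_seed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    force(code)
  }
  withr_seed(seed, {
    g <- rep(seq_len(q), each = r)
    y <- rnorm(q, 0, sqrt(s2g))[g] + rnorm(q * r, 0, sqrt(s2e))
    list(y = y, g = paste0("g", g))
  })
}

# closed-form ANOVA variance components for balanced one-way data
anova_oneway <- function(y, g, r) {
  gm <- tapply(y, g, mean)
  mse <- sum((y - gm[g])^2) / (length(y) - length(gm))
  msb <- r * sum((gm - mean(y))^2) / (length(gm) - 1)
  c(s2g = (msb - mse) / r, s2e = mse)
}

# brute-force elastic-net solution by enumerating active sets and signs;
# valid for small p, independent of any path algorithm
enet_qp_oracle <- function(P, G, lambda, alpha = 1) {
  p <- length(G)
  stopifnot(p <= 8)
  best <- NULL
  for (mask in 0:(2^p - 1)) {
    A <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (!length(A)) {
      if (all(abs(G) <= lambda * alpha + 1e-10)) return(numeric(p))
      next
    }
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(A))))
    for (si in seq_len(nrow(signs))) {
      s <- signs[si, ]
      M <- P[A, A, drop = FALSE] + diag(lambda * (1 - alpha), length(A))
      bA <- tryCatch(solve(M, G[A] - lambda * alpha * s),
                     error = function(e) NULL)
      if (is.null(bA)) next
      if (any(sign(bA) != s)) next
      b <- numeric(p)
      b[A] <- bA
      r <- G - as.numeric(P %*% b)
      inA <- setdiff(seq_len(p), A)
      if (length(inA) && any(abs(r[inA]) > lambda * alpha + 1e-8)) next
      best <- b
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) stop("oracle found no KKT point")
  best
}

# element-wise two-pass covariance
two_pass_cov <- function(X) {
  p <- ncol(X)
  n <- nrow(X)
  out <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- X[, i] - mean(X[, i])
    xj <- X[, j] - mean(X[, j])
    out[i, j] <- sum(xi * xj) / (n - 1)
  }
  out
}

# small simulated dataset, pre-adjusted and standardized, ready for tuning
adjusted_sim <- function(truth, n_trials = 20, genotypes_per_trial = 10,
                         replicates = 2, subblocks = 2, seed = 1,
                         fence = 3, adjust_bands = FALSE) {
  sim <- sim_trials(truth, n_trials = n_trials,
                    genotypes_per_trial = genotypes_per_trial,
                    replicates = replicates, subblocks = subblocks,
                    seed = seed)
  adj <- preadjust(sim$pheno)
  fs <- filter_standardize(adj, fence = fence)
  k <- fs$retained
  bands <- if (adjust_bands) preadjust_bands(sim$pheno, sim$bands)
           else sim$bands
  list(y = fs$values[k], X = bands[k, , drop = FALSE],
       genotype = sim$pheno$genotype[k], trial = sim$pheno$trial[k],
       sim = sim, scale = fs$scale)
}
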