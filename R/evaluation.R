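# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Trial-blocked training/testing partitions
#'
#' Randomly assigns complete trials to training and testing sets, so that no
#' plot of any trial appears on both sides; this mimics calibrating index
#' weights on historical trials and applying them to future ones.
#'
#' @param trial_ids vector of trial labels (duplicates allowed; the unique
#'   set is partitioned).
#' @param n_train_trials number of trials assigned to training (default:
#'   two thirds, rounded).
#' @param n_partitions number of independent random partitions.
#' @param seed integer seed making the partition sequence reproducible.
#' @return list of partitions, each a list with `train` and `test` trial
#'   label vectors and the replicate number `id`.
#' @export
make_partitions <- function(trial_ids, n_train_trials = NULL,
                            n_partitions = 100, seed = 1) {
  trials <- sort(unique(as.character(trial_ids)))
  nt <- length(trials)
  if (nt < 2L) stop("need at least 2 trials to partition")
  if (is.null(n_train_trials)) n_train_trials <- round(2 * nt / 3)
  if (n_train_trials < 1L || n_train_trials >= nt)
    stop("n_train_trials must be in [1, ", nt - 1L, "], got ", n_train_trials)
  with_seed(seed, lapply(seq_len(n_partitions), function(i) {
    tr <- sort(sample(trials, n_train_trials))
    list(train = tr, test = setdiff(trials, tr), id = i)
  }))
}

#' Indirect-selection accuracy of an index on a testing set
#'
#' From index values and target phenotypes of testing-set plots, estimates by
#' one-factor REML the heritability of the index (`h2_I`), of the target
#' (`h2_y`), the genetic correlation `r_g` between the two (sum-of-traits
#' genetic covariance divided by the genetic SDs), and derives the accuracy of
#' indirect selection `Acc = sqrt(h2_I) * r_g` and the efficiency relative to
#' mass phenotypic selection `RE = sqrt(h2_I / h2_y) * r_g`. Estimated `r_g`
#' outside `[-1, 1]` (possible with method-of-moments components) is clipped
#' and flagged.
#'
#' @param index numeric index values on testing plots.
#' @param target numeric target phenotypes on the same plots.
#' @param genotype genotype labels of the plots.
#' @return object of class `"si_eval"`: list with `h2_I`, `h2_y`, `r_g`,
#'   `acc`, `re`, `clipped` and `undefined` flags, and the underlying genetic
#'   (co)variances.
#' @export
evaluate_index <- function(index, target, genotype) {
  if (length(index) != length(target))
    stop("index and target must share plot records")
  fI <- reml_onefactor(index, genotype)
  fy <- reml_onefactor(target, genotype)
  fs <- reml_onefactor(index + target, genotype)
  G_Iy <- 0.5 * (fs$sigma2_g - fI$sigma2_g - fy$sigma2_g)
  h2_I <- if (fI$sigma2_g + fI$sigma2_e > 0)
    min(max(fI$sigma2_g / (fI$sigma2_g + fI$sigma2_e), 0), 1) else NA_real_
  h2_y <- if (fy$sigma2_g + fy$sigma2_e > 0)
    min(max(fy$sigma2_g / (fy$sigma2_g + fy$sigma2_e), 0), 1) else NA_real_
  undefined <- fI$sigma2_g <= 0 || fy$sigma2_g <= 0
  clipped <- FALSE
  if (undefined) {
    r_g <- acc <- re <- NA_real_
  } else {
    r_g <- G_Iy / sqrt(fI$sigma2_g * fy$sigma2_g)
    if (abs(r_g) > 1) {
      r_g <- sign(r_g)
      clipped <- TRUE
    }
    acc <- sqrt(h2_I) * r_g
    re <- if (h2_y > 0) sqrt(h2_I / h2_y) * r_g else NA_real_
  }
  structure(list(h2_I = h2_I, h2_y = h2_y, r_g = r_g, acc = acc, re = re,
                 clipped = clipped, undefined = undefined,
                 sigma2_g_I = fI$sigma2_g, sigma2_g_y = fy$sigma2_g,
                 G_Iy = G_Iy),
            class = "si_eval")
}

#' @export
print.si_eval <- function(x, ...) {
  cat("Indirect-selection evaluation\n")
  if (x$undefined) {
    cat("  undefined: zero genetic variance of index or target\n")
  } else {
    cat(sprintf("  h2_I = %.4f  h2_y = %.4f  r_g = %.4f%s\n",
                x$h2_I, x$h2_y, x$r_g, if (x$clipped) " (clipped)" else ""))
    cat(sprintf("  Acc  = %.4f  RE   = %.4f\n", x$acc, x$re))
  }
  invisible(x)
}

#' Mean, SD and normal-approximation confidence interval across partitions
#'
#' @param values numeric vector of a per-partition statistic.
#' @param level confidence level (default 0.95).
#' @return list with `mean`, `sd`, `n`, `ci_lower`, `ci_upper`
#'   (mean +/- z * sd / sqrt(n)).
#' @export
summarize_partitions <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) stop("need at least 2 partitions to summarize")
  m <- mean(values)
  s <- stats::sd(values)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(mean = m, sd = s, n = n,
       ci_lower = m - z * s / sqrt(n), ci_upper = m + z * s / sqrt(n))
}

# standardize columns by training statistics; scale from training only
train_scale <- function(X_tr) {
  list(center = colMeans(X_tr),
       scale = apply(X_tr, 2L, stats::sd))
}
apply_scale <- function(X, sc) {
  X <- sweep(X, 2L, sc$center, "-")
  sweep(X, 2L, pmax(sc$scale, 1e-12), "/")
}

#' Tune a regularized selection index by trial-blocked accuracy
#'
#' For each training/testing partition, estimates the training phenotypic
#' covariance matrix and genetic covariances, fits the requested index family
#' along its complexity grid (penalty `lambda` for L1/EN/L2, number of PCs
#' `q` for PC), applies each solution to the testing plots and estimates the
#' accuracy of indirect selection there. The tuning curve aggregates the
#' per-partition accuracies; the optimum is the grid point maximizing mean
#' accuracy (ties broken toward the least complex solution) and is refit on
#' the full data.
#'
#' Band standardization scales are always computed on the training plots and
#' applied unchanged to the testing plots.
#'
#' @param y adjusted, standardized target phenotypes (all plots).
#' @param X n x p matrix of adjusted band phenotypes (all plots).
#' @param genotype,trial genotype and trial labels per plot.
#' @param method one of `"L1"`, `"EN"`, `"L2"`, `"PC"`.
#' @param partitions list of partitions from [make_partitions()].
#' @param lambda decreasing penalty grid (L1/EN/L2); default derived from the
#'   first partition's training genetic covariances via [si_lambda_grid()].
#' @param alpha elastic-net mixing parameter (EN only).
#' @param q_grid increasing grid of PC counts (PC only); default
#'   `1:min(p, 20)` extended sparsely to the rank.
#' @param gwy how to obtain PC-level genetic covariances: `"scores"`
#'   (estimate on the PC scores by the sum-of-traits model; default) or
#'   `"rotate"` (rotate band-level estimates).
#' @param standardize standardize bands by training SDs (default TRUE).
#' @param keep_coefs retain the per-partition coefficient matrices (useful for
#'   auditing that coefficients depend on training data only).
#' @return object of class `"si_tune"`: the tuning `curve` data frame
#'   (complexity, mean/SD of accuracy, heritability and genetic correlation),
#'   the optimal grid point, the refit `optimal` index (`"psi"`), and
#'   per-partition accuracy matrix.
#' @export
tune_si <- function(y, X, genotype, trial,
                    method = c("L1", "EN", "L2", "PC"),
                    partitions, lambda = NULL, alpha = 1, q_grid = NULL,
                    gwy = c("scores", "rotate"), standardize = TRUE,
                    keep_coefs = FALSE) {
  method <- match.arg(method)
  gwy <- match.arg(gwy)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(genotype) == n, length(trial) == n)
  if (length(partitions) < 1L) stop("need at least one partition")
  trial <- as.character(trial)
  alpha_eff <- switch(method, L1 = 1, EN = alpha, L2 = 0, PC = NA_real_)

  grid_of <- function(part) {
    tr <- trial %in% part$train
    sc <- train_scale(X[tr, , drop = FALSE])
    Xtr <- if (standardize) apply_scale(X[tr, , drop = FALSE], sc)
           else sweep(X[tr, , drop = FALSE], 2L, sc$center, "-")
    ytr <- y[tr] / stats::sd(y[tr])
    list(tr = tr, sc = sc, Xtr = Xtr, ytr = ytr)
  }

  if (method %in% c("L1", "EN", "L2") && is.null(lambda)) {
    p1 <- grid_of(partitions[[1]])
    G1 <- gen_covariance_panel(p1$ytr, p1$Xtr, genotype[p1$tr])$G
    lambda <- si_lambda_grid(G1, alpha = max(alpha_eff, 1e-3), nlambda = 30,
                             min_ratio = 0.01)
  }
  if (method == "PC" && is.null(q_grid)) {
    r <- min(ncol(X), n - 1L)
    q_grid <- sort(unique(c(1:min(r, 20),
                            round(exp(seq(log(20), log(r), length.out = 10))))))
    q_grid <- q_grid[q_grid >= 1 & q_grid <= r]
  }
  npts <- if (method == "PC") length(q_grid) else length(lambda)
  if (npts < 1L) stop("empty complexity grid")

  acc <- h2I <- rg <- nact <- matrix(NA_real_, length(partitions), npts)
  clips <- 0L
  part_coefs <- if (keep_coefs) vector("list", length(partitions)) else NULL
  for (ip in seq_along(partitions)) {
    part <- partitions[[ip]]
    gp <- grid_of(part)
    te <- !gp$tr
    Xte <- if (standardize) apply_scale(X[te, , drop = FALSE], gp$sc)
           else sweep(X[te, , drop = FALSE], 2L, gp$sc$center, "-")
    yte <- y[te]
    gte <- genotype[te]
    if (method %in% c("L1", "EN", "L2")) {
      Px <- phen_cov(gp$Xtr)
      G <- gen_covariance_panel(gp$ytr, gp$Xtr, genotype[gp$tr])$G
      B <- if (method == "L2") {
        vapply(lambda, function(l) l2_psi(Px, G, l)$beta, numeric(ncol(X)))
      } else {
        en_psi(Px, G, lambda = lambda, alpha = alpha_eff)$beta
      }
      if (is.null(dim(B))) B <- matrix(B, ncol = npts)
      if (keep_coefs) part_coefs[[ip]] <- B
      for (k in seq_len(npts)) {
        b <- B[, k]
        nact[ip, k] <- sum(b != 0)
        if (all(b == 0)) next
        ev <- evaluate_index(as.numeric(Xte %*% b), yte, gte)
        if (!ev$undefined) {
          acc[ip, k] <- ev$acc; h2I[ip, k] <- ev$h2_I; rg[ip, k] <- ev$r_g
          if (ev$clipped) clips <- clips + 1L
        }
      }
    } else {
      dec <- spectral(gp$Xtr, center = FALSE)  # already centered on training
      qmax <- max(q_grid)
      rank <- sum(dec$d > 1e-10 * dec$d[1])
      G_wy <- if (gwy == "scores") {
        W <- pc_scores(dec, min(qmax, rank))
        gen_covariance_panel(gp$ytr, W, genotype[gp$tr])$G
      } else {
        Gb <- gen_covariance_panel(gp$ytr, gp$Xtr, genotype[gp$tr])$G
        rotate_gencov(dec, Gb)
      }
      if (keep_coefs) part_coefs[[ip]] <- matrix(NA_real_, ncol(X), npts)
      for (k in seq_len(npts)) {
        qk <- q_grid[k]
        if (qk > rank) next
        b <- pc_si(dec, G_wy, qk)$beta
        if (keep_coefs) part_coefs[[ip]][, k] <- b
        nact[ip, k] <- sum(b != 0)
        ev <- evaluate_index(as.numeric(Xte %*% b), yte, gte)
        if (!ev$undefined) {
          acc[ip, k] <- ev$acc; h2I[ip, k] <- ev$h2_I; rg[ip, k] <- ev$r_g
          if (ev$clipped) clips <- clips + 1L
        }
      }
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  if (all(!is.finite(mean_acc)))
    stop("accuracy undefined at every grid point")
  # complexity axis: increasing model complexity
  complexity <- if (method == "PC") q_grid else seq_len(npts)
  best_val <- max(mean_acc, na.rm = TRUE)
  cand <- which(mean_acc >= best_val - 1e-12)
  best_idx <- cand[1]  # grids run from least to most complex
  curve <- data.frame(
    complexity = complexity,
    lambda = if (method == "PC") NA_real_ else lambda,
    q = if (method == "PC") q_grid else NA_integer_,
    n_active = colMeans(nact, na.rm = TRUE),
    mean_acc = mean_acc,
    sd_acc = apply(acc, 2L, stats::sd, na.rm = TRUE),
    mean_h2I = colMeans(h2I, na.rm = TRUE),
    sd_h2I = apply(h2I, 2L, stats::sd, na.rm = TRUE),
    mean_rg = colMeans(rg, na.rm = TRUE),
    sd_rg = apply(rg, 2L, stats::sd, na.rm = TRUE))

  # refit the optimum on the full data
  sc_all <- train_scale(X)
  X_all <- if (standardize) apply_scale(X, sc_all)
           else sweep(X, 2L, sc_all$center, "-")
  y_all <- y / stats::sd(y)
  optimal <- if (method %in% c("L1", "EN", "L2")) {
    Px <- phen_cov(X_all)
    G <- gen_covariance_panel(y_all, X_all, genotype)$G
    if (method == "L2") l2_psi(Px, G, lambda[best_idx])
    else {
      pb <- en_psi(Px, G, lambda = lambda[seq_len(best_idx)], alpha = alpha_eff)
      new_psi(pb$beta[, best_idx], method, lambda = lambda[best_idx],
              alpha = alpha_eff, labels = colnames(X))
    }
  } else {
    dec <- spectral(X_all, center = FALSE)
    rank <- sum(dec$d > 1e-10 * dec$d[1])
    qb <- min(q_grid[best_idx], rank)
    G_wy <- if (gwy == "scores") {
      gen_covariance_panel(y_all, pc_scores(dec, qb), genotype)$G
    } else {
      rotate_gencov(dec, gen_covariance_panel(y_all, X_all, genotype)$G)
    }
    pc_si(dec, G_wy, qb)
  }
  structure(list(curve = curve, method = method,
                 best = list(index = best_idx,
                             lambda = if (method == "PC") NA_real_
                                      else lambda[best_idx],
                             q = if (method == "PC") q_grid[best_idx]
                                 else NA_integer_,
                             mean_acc = mean_acc[best_idx]),
                 optimal = optimal, acc = acc,
                 n_partitions = length(partitions), clips = clips,
                 part_coefs = part_coefs, scale = sc_all),
            class = "si_tune")
}

#' @export
print.si_tune <- function(x, ...) {
  cat("Selection-index tuning (", x$method, "), ", x$n_partitions,
      " partitions, ", nrow(x$curve), " grid points\n", sep = "")
  if (x$method == "PC") {
    cat(sprintf("  optimum: q = %d, mean Acc = %.4f\n",
                x$best$q, x$best$mean_acc))
  } else {
    cat(sprintf("  optimum: lambda = %.6g (%d active bands), mean Acc = %.4f\n",
                x$best$lambda, length(x$optimal$active), x$best$mean_acc))
  }
  if (x$clips > 0) cat("  genetic correlations clipped to [-1,1]: ", x$clips,
                       " times\n", sep = "")
  invisible(x)
}

#' @export
plot.si_tune <- function(x, ...) {
  cv <- x$curve
  xs <- cv$n_active
  graphics::plot(xs, cv$mean_acc, type = "b", pch = 16, col = "purple",
                 ylim = range(c(cv$mean_acc, sqrt(cv$mean_h2I), cv$mean_rg),
                              na.rm = TRUE),
                 xlab = if (x$method == "PC") "number of PCs"
                        else "active bands",
                 ylab = "value", main = paste0(x$method, " tuning curve"), ...)
  graphics::lines(xs, sqrt(cv$mean_h2I), type = "b", pch = 1, col = "darkgreen")
  graphics::lines(xs, cv$mean_rg, type = "b", pch = 2, col = "orange")
  graphics::legend("bottomright", bty = "n",
                   legend = c("Acc", "sqrt(h2_I)", "r_g"),
                   col = c("purple", "darkgreen", "orange"), pch = c(16, 1, 2))
  invisible(x)
}

#' Normalized-difference vegetation indices from reflectance bands
#'
#' `RNDVI = (NIR - Red)/(NIR + Red)` and `GNDVI = (NIR - Green)/(NIR + Green)`,
#' where each band value is the mean reflectance over a configured wavelength
#' window.
#'
#' @param X n x p matrix of raw reflectance values.
#' @param wavelength length-p vector of band wavelengths in nm.
#' @param kind `"RNDVI"` or `"GNDVI"`.
#' @param windows named list of wavelength windows in nm (defaults: red
#'   660-680, green 540-560, nir 780-850).
#' @return numeric vector of per-plot index values.
#' @export
vegetation_index <- function(X, wavelength, kind = c("RNDVI", "GNDVI"),
                             windows = list(red = c(660, 680),
                                            green = c(540, 560),
                                            nir = c(780, 850))) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  if (ncol(X) != length(wavelength))
    stop("wavelength metadata must have one entry per band")
  band_mean <- function(win_name) {
    win <- windows[[win_name]]
    sel <- wavelength >= win[1] & wavelength <= win[2]
    if (!any(sel))
      stop("no bands cover the ", win_name, " window [", win[1], ", ", win[2],
           "] nm")
    rowMeans(X[, sel, drop = FALSE])
  }
  nir <- band_mean("nir")
  other <- band_mean(if (kind == "RNDVI") "red" else "green")
  den <- nir + other
  if (any(den == 0))
    stop(kind, " undefined: NIR + ",
         if (kind == "RNDVI") "Red" else "Green",
         " reflectance is zero for ", sum(den == 0), " plot(s)")
  (nir - other) / den
}

#' L1-penalized phenotypic prediction baseline
#'
#' Same covariance-form solver as the penalized selection index, but with the
#' genetic covariances replaced by phenotypic covariances `X'y/(n-1)`: the
#' coefficients predict the phenotype rather than the genetic merit. This is
#' the contrast between selection indices (genetic covariance inputs) and
#' phenotypic prediction (phenotypic covariance inputs).
#'
#' @param X n x p matrix of (standardized) band phenotypes.
#' @param y standardized target phenotypes.
#' @param lambda decreasing penalty grid; default from [si_lambda_grid()].
#' @param alpha elastic-net mixing parameter (default 1, the LASSO).
#' @param ... passed to [en_psi()].
#' @return a `"psi_path"` object.
#' @export
l1_phen <- function(X, y, lambda = NULL, alpha = 1, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("X and y must share plot records")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  yc <- y - mean(y)
  Px <- phen_cov(X)
  Gph <- as.numeric(crossprod(Xc, yc)) / (n - 1)
  names(Gph) <- colnames(X)
  out <- en_psi(Px, Gph, lambda = lambda, alpha = alpha, ...)
  attr(out, "covariance") <- "phenotypic"
  out
}
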