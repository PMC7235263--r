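#' Construct a known genetic/environmental covariance truth for simulation
#'
#' Builds the population covariance structure of a band panel plus target
#' trait with the features of real spectral data: a low-rank genetic factor
#' structure (n_factors smooth loadings over wavelength), smooth band-to-band
#' environmental correlation decaying with wavelength distance, unit band
#' phenotypic variances with prescribed band heritabilities, and a genetic
#' correlation profile linking bands to the target.
#'
#' The target's genetic effect is represented inside the same factor space
#' (`g_y = w'f + delta`), so the joint (p+1)-dimensional genetic covariance is
#' positive semi-definite by construction. A requested correlation profile
#' outside the factor space is projected onto it; the achieved profile is
#' stored in the result. A profile whose projection would require more genetic
#' variance than `h2_target` allows raises an error stating the violated
#' bound.
#'
#' @param p number of bands.
#' @param n_factors rank of the genetic factor structure.
#' @param decay correlation length of the smooth band-to-band structure, as a
#'   fraction of the spectral range (0 = independent bands).
#' @param h2_bands band heritabilities in (0, 1], recycled to length p.
#' @param h2_target target heritability in (0, 1].
#' @param r_g_profile length-p vector of requested genetic correlations
#'   between each band and the target.
#' @param nugget fraction of each band's environmental variance that is
#'   independent across bands (sensor noise); keeps the phenotypic covariance
#'   well-conditioned.
#' @param wavelength band wavelengths in nm (default 392-850, evenly spaced).
#' @param nuisance named variances of the additive trial, replicate and
#'   sub-block effects used by [sim_trials()].
#' @return object of class `"si_truth"` with `G_x`, `E_x`, `G_xy` (achieved),
#'   `sigma2_gy`, `sigma2_ey`, the factor loadings, and the design defaults.
#' @export
sim_truth <- function(p, n_factors = 5, decay = 0.08,
                      h2_bands = 0.5, h2_target = 0.5,
                      r_g_profile = NULL, nugget = 0.05,
                      wavelength = seq(392, 850, length.out = p),
                      nuisance = c(trial = 0.2, rep = 0.05, subblock = 0.05)) {
  stopifnot(p >= 1, n_factors >= 1, n_factors <= p, decay >= 0,
            nugget >= 0, nugget <= 1)
  h2_bands <- rep_len(h2_bands, p)
  if (any(h2_bands <= 0 | h2_bands > 1)) stop("band heritabilities must be in (0, 1]")
  if (h2_target <= 0 || h2_target > 1) stop("h2_target must be in (0, 1]")
  pos <- if (p > 1) (wavelength - min(wavelength)) / diff(range(wavelength))
         else 0
  centers <- if (n_factors > 1) seq(0, 1, length.out = n_factors) else 0.5
  if (decay > 0) {
    L0 <- outer(pos, centers, function(a, b) exp(-(a - b)^2 / (2 * decay^2)))
  } else {
    nearest <- vapply(pos, function(x) which.min(abs(centers - x)), integer(1))
    L0 <- matrix(0, p, n_factors)
    L0[cbind(seq_len(p), nearest)] <- 1
  }
  L <- L0 / sqrt(rowSums(L0^2))            # unit rows => unit-diagonal R_g
  R_g <- tcrossprod(L)
  sg <- sqrt(h2_bands)
  G_x <- R_g * tcrossprod(sg)
  R_e <- if (decay > 0) {
    K <- outer(pos, pos, function(a, b) exp(-(a - b)^2 / (2 * decay^2)))
    (1 - nugget) * K + nugget * diag(p)
  } else diag(p)
  se <- sqrt(1 - h2_bands)
  E_x <- R_e * tcrossprod(se)
  sigma2_gy <- h2_target
  sigma2_ey <- 1 - h2_target
  if (is.null(r_g_profile)) r_g_profile <- rep(0, p)
  if (length(r_g_profile) != p) stop("r_g_profile must have length p")
  G_req <- r_g_profile * sg * sqrt(sigma2_gy)
  Lstar <- L * sg                            # G_x = Lstar %*% t(Lstar)
  # least-squares projection of the requested profile onto the factor space
  sv <- svd(Lstar)
  pos_d <- sv$d > 1e-10 * sv$d[1]
  w <- sv$v[, pos_d, drop = FALSE] %*%
    ((crossprod(sv$u[, pos_d, drop = FALSE], G_req)) / sv$d[pos_d])
  w <- as.numeric(w)
  expl <- sum(w^2)
  if (expl > sigma2_gy + 1e-12)
    stop("infeasible genetic-correlation profile: it requires ",
         format(expl), " of target genetic variance but sigma2_gy = ",
         format(sigma2_gy),
         "; reduce |r_g| or increase h2_target")
  G_xy <- as.numeric(Lstar %*% w)
  labels <- paste0("b", seq_len(p))
  dimnames(G_x) <- dimnames(E_x) <- list(labels, labels)
  names(G_xy) <- labels
  joint <- rbind(cbind(G_x, G_xy), c(G_xy, sigma2_gy))
  ev_min <- min(eigen(joint, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) stop("internal error: joint genetic covariance not PSD")
  structure(list(G_x = G_x, E_x = E_x, G_xy = G_xy,
                 G_xy_requested = stats::setNames(G_req, labels),
                 sigma2_gy = sigma2_gy, sigma2_ey = sigma2_ey,
                 h2_bands = h2_bands, h2_target = h2_target,
                 w = w, Lstar = Lstar, n_factors = n_factors, decay = decay,
                 delta_var = sigma2_gy - expl,
                 wavelength = wavelength, labels = labels,
                 nuisance = nuisance),
            class = "si_truth")
}

#' @export
print.si_truth <- function(x, ...) {
  cat("Synthetic truth: p =", length(x$labels),
      "bands, genetic rank", x$n_factors, "\n")
  cat(sprintf("  h2_target = %.3f, mean band h2 = %.3f, decay = %.3f\n",
              x$h2_target, mean(x$h2_bands), x$decay))
  cat(sprintf("  max |achieved r_g| = %.3f\n",
              max(abs(x$G_xy) / (sqrt(diag(x$G_x)) * sqrt(x$sigma2_gy)))))
  invisible(x)
}

# draws from independent substreams so that e.g. adding bands does not
# perturb the genotype effects
substream <- function(seed, k) (as.integer(seed) %% 1000003L) * 2011L + 97L * k

#' Simulate multi-trial phenotype and reflectance records
#'
#' Draws a full field-trial dataset under a known truth: genotypes nested in
#' trials, arranged in replicates subdivided into sub-blocks (alpha-lattice
#' style); genotype effects from the joint (p+1)-dimensional genetic
#' covariance; plot-level band deviations from `E_x` (independent of the
#' genetic effects); additive iid trial, replicate and sub-block effects with
#' the truth's declared variances, drawn independently per trait.
#'
#' Defaults mirror a large wheat phenotyping design: 39 trials of 28
#' genotypes in 3 replicates and 6 sub-blocks.
#'
#' @param truth a `"si_truth"` object.
#' @param n_trials,genotypes_per_trial,replicates,subblocks design sizes.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return object of class `"si_sim"`: `pheno` (long-format target records
#'   with genotype/trial/rep/subblock columns), `bands` (n x p reflectance
#'   matrix aligned with `pheno` rows), genotype-level true effects
#'   (`g_y`, `g_x`), and the generating `truth`.
#' @export
sim_trials <- function(truth, n_trials = 39, genotypes_per_trial = 28,
                       replicates = 3, subblocks = 6, seed = 1) {
  stopifnot(inherits(truth, "si_truth"),
            n_trials >= 1, genotypes_per_trial >= 1, replicates >= 1,
            subblocks >= 1)
  p <- length(truth$labels)
  k <- truth$n_factors
  n_geno <- n_trials * genotypes_per_trial
  geno_ids <- paste0("T", rep(seq_len(n_trials), each = genotypes_per_trial),
                     "G", sprintf("%02d", seq_len(genotypes_per_trial)))
  # genotype effects: f ~ N(0, I_k); g_x = Lstar f; g_y = w'f + delta
  Fm <- with_seed(substream(seed, 1L),
                  matrix(rnorm(n_geno * k), n_geno, k))
  delta <- with_seed(substream(seed, 2L),
                     rnorm(n_geno, 0, sqrt(max(truth$delta_var, 0))))
  g_x <- Fm %*% t(truth$Lstar)               # n_geno x p
  g_y <- as.numeric(Fm %*% truth$w) + delta
  rownames(g_x) <- names(g_y) <- geno_ids

  n <- n_geno * replicates
  geno <- rep(geno_ids, times = replicates)
  trial <- rep(rep(paste0("T", seq_len(n_trials)), each = genotypes_per_trial),
               times = replicates)
  repl <- rep(paste0("R", seq_len(replicates)), each = n_geno)
  # sub-block assignment: genotypes shuffled into sub-blocks per replicate
  sb <- with_seed(substream(seed, 3L), {
    out <- character(n)
    idx <- 0L
    for (r in seq_len(replicates)) for (t in seq_len(n_trials)) {
      m <- genotypes_per_trial
      bl <- rep_len(seq_len(subblocks), m)
      out[idx + seq_len(m)] <- paste0("B", sample(bl))
      idx <- idx + m
    }
    out
  })
  nu <- truth$nuisance
  tr_eff_y <- with_seed(substream(seed, 4L),
                        rnorm(n_trials, 0, sqrt(nu[["trial"]])))
  rep_eff_y <- with_seed(substream(seed, 5L),
                         matrix(rnorm(n_trials * replicates, 0,
                                      sqrt(nu[["rep"]])),
                                n_trials, replicates))
  sb_lab <- paste(trial, repl, sb, sep = ":")
  sb_lev <- sort(unique(sb_lab))
  sb_eff_y <- with_seed(substream(seed, 6L),
                        stats::setNames(rnorm(length(sb_lev), 0,
                                              sqrt(nu[["subblock"]])),
                                        sb_lev))
  eps_y <- with_seed(substream(seed, 7L),
                     rnorm(n, 0, sqrt(truth$sigma2_ey)))
  ti <- rep(rep(seq_len(n_trials), each = genotypes_per_trial),
            times = replicates)
  ri <- rep(seq_len(replicates), each = n_geno)
  y <- g_y[geno] + tr_eff_y[ti] + rep_eff_y[cbind(ti, ri)] +
    sb_eff_y[sb_lab] + eps_y

  # band records: genetic + structured environmental + per-band nuisance
  Ex_sqrt <- {
    ee <- eigen(truth$E_x, symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    ee$vectors %*% (sqrt(ev) * t(ee$vectors))
  }
  E_dev <- with_seed(substream(seed, 8L),
                     matrix(rnorm(n * p), n, p) %*% Ex_sqrt)
  tr_eff_x <- with_seed(substream(seed, 9L),
                        matrix(rnorm(n_trials * p, 0, sqrt(nu[["trial"]])),
                               n_trials, p))
  rep_lab <- paste(trial, repl, sep = ":")
  rep_lev <- sort(unique(rep_lab))
  rep_eff_x <- with_seed(substream(seed, 10L),
                         matrix(rnorm(length(rep_lev) * p, 0,
                                      sqrt(nu[["rep"]])),
                                length(rep_lev), p,
                                dimnames = list(rep_lev, NULL)))
  sb_eff_x <- with_seed(substream(seed, 11L),
                        matrix(rnorm(length(sb_lev) * p, 0,
                                     sqrt(nu[["subblock"]])),
                               length(sb_lev), p,
                               dimnames = list(sb_lev, NULL)))
  bands <- g_x[geno, , drop = FALSE] + E_dev + tr_eff_x[ti, , drop = FALSE] +
    rep_eff_x[rep_lab, , drop = FALSE] + sb_eff_x[sb_lab, , drop = FALSE]
  colnames(bands) <- truth$labels
  rownames(bands) <- NULL

  pheno <- data.frame(genotype = geno, trial = trial, rep = repl,
                      subblock = sb, env = "E1", trait = "target",
                      value = as.numeric(y), stringsAsFactors = FALSE)
  structure(list(pheno = pheno, bands = bands, g_y = g_y, g_x = g_x,
                 truth = truth, seed = seed,
                 design = c(n_trials = n_trials,
                            genotypes_per_trial = genotypes_per_trial,
                            replicates = replicates, subblocks = subblocks)),
            class = "si_sim")
}

#' @export
print.si_sim <- function(x, ...) {
  d <- x$design
  cat("Simulated dataset:", nrow(x$pheno), "plots =",
      d["n_trials"], "trials x", d["genotypes_per_trial"], "genotypes x",
      d["replicates"], "replicates;", ncol(x$bands), "bands (seed",
      x$seed, ")\n")
  invisible(x)
}

#' Closed-form accuracy of indirect selection under the generating model
#'
#' For fixed index weights `beta`, the population correlation between the
#' index `x'beta` and the target's genetic merit is
#' `Acc = beta'G_xy / sqrt(beta'(G_x + E_x) beta * sigma2_gy)`; it is
#' invariant to positive rescaling of `beta`. This is the oracle against which
#' estimated accuracies and the benefit of regularization are judged on
#' synthetic data.
#'
#' @param beta index weights (a numeric vector or `"psi"` object).
#' @param truth the generating `"si_truth"`.
#' @return the true accuracy (scalar in `[-1, 1]`).
#' @export
true_accuracy <- function(beta, truth) {
  stopifnot(inherits(truth, "si_truth"))
  b <- if (inherits(beta, "psi")) beta$beta else as.numeric(beta)
  if (length(b) != length(truth$G_xy)) stop("beta has the wrong length")
  if (all(b == 0)) stop("accuracy undefined for beta = 0")
  P <- truth$G_x + truth$E_x
  denom <- sqrt(as.numeric(t(b) %*% P %*% b) * truth$sigma2_gy)
  if (denom <= 0) stop("accuracy undefined: zero index variance")
  sum(b * truth$G_xy) / denom
}

#' Population-optimal standard index from the truth
#'
#' `beta = (G_x + E_x)^{-1} G_xy`, the best linear predictor of the target's
#' genetic merit when the population covariances are known; its
#' [true_accuracy()] upper-bounds that of every other weight vector.
#'
#' @param truth a `"si_truth"` object.
#' @return a `"psi"` object.
#' @export
true_standard_si <- function(truth) {
  stopifnot(inherits(truth, "si_truth"))
  standard_si(truth$G_x + truth$E_x, truth$G_xy)
}
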