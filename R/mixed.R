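#' Validate a long-format phenotype table
#'
#' Checks that a data frame of plot records carries the design columns the
#' pre-adjustment model needs: a `genotype` and a `trial` column are mandatory
#' (non-missing in every record), `rep`, `subblock`, `timepoint` and `env` are
#' optional, and exactly one numeric response column (`value` by default) holds
#' the trait.
#'
#' @param data data frame of plot records.
#' @param response name of the trait column.
#' @return `data` invisibly, with design columns coerced to character.
#' @export
validate_phenotypes <- function(data, response = "value") {
  stopifnot(is.data.frame(data))
  for (col in c("genotype", "trial", response)) {
    if (!col %in% names(data))
      stop("phenotype table lacks required column '", col, "'")
  }
  for (col in c("genotype", "trial")) {
    if (anyNA(data[[col]]))
      stop("missing values in required column '", col, "'")
    data[[col]] <- as.character(data[[col]])
  }
  for (col in c("rep", "subblock", "timepoint", "env")) {
    if (col %in% names(data)) data[[col]] <- as.character(data[[col]])
  }
  if (!is.numeric(data[[response]]))
    stop("response column '", response, "' must be numeric")
  invisible(data)
}

# Build one grouping factor per model term. Terms are colon-joined column
# names ("trial:rep" = replicate nested in trial); nesting is realised by
# pasting the parent labels into the level label.
term_factor <- function(data, term) {
  cols <- strsplit(term, ":", fixed = TRUE)[[1]]
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("factor term '", term, "' refers to missing column(s): ",
         paste(missing_cols, collapse = ", "))
  lab <- do.call(paste, c(lapply(cols, function(cl) as.character(data[[cl]])),
                          sep = ":"))
  factor(lab, levels = sort(unique(lab)))
}

#' Fit an all-random-effects model to plot records
#'
#' Fits the pre-adjustment mixed model in which every design factor
#' (genotype, trial, replicate within trial, sub-block within replicate, and
#' optionally time-point) is a random effect with its own iid normal variance,
#' plus a fixed intercept, by REML through [lme4::lmer()]. Rows are put in a
#' canonical order before fitting so that the result is invariant to record
#' permutation.
#'
#' @param data phenotype table (see [validate_phenotypes()]).
#' @param factors character vector of model terms; nested factors are written
#'   as colon-joined column names, e.g. `"trial:rep"`.
#' @param response name of the trait column.
#' @return An object of class `"ranef_fit"`: a list with the REML variance
#'   components (`varcomp`, one entry per term plus `"residual"`; boundary
#'   estimates reported as exactly 0), per-level BLUPs (`blup`, a named vector
#'   per term), the overall mean `mu`, the restricted log-likelihood, and a
#'   convergence flag.
#' @export
fit_random_model <- function(data,
                             factors = c("genotype", "trial", "trial:rep",
                                         "trial:rep:subblock"),
                             response = "value") {
  data <- validate_phenotypes(data, response)
  y <- data[[response]]
  if (anyNA(y)) {
    keep <- !is.na(y)
    data <- data[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  if (n < 3L) stop("need at least 3 records to fit the random-effects model")
  fct <- lapply(factors, function(tm) term_factor(data, tm))
  names(fct) <- factors
  for (tm in factors) {
    if (nlevels(fct[[tm]]) < 2L)
      stop("factor '", tm, "' has a single level; cannot estimate its variance")
  }
  mf <- data.frame(.y = y)
  gen_names <- paste0(".f", seq_along(factors))
  for (i in seq_along(factors)) mf[[gen_names[i]]] <- fct[[i]]
  # canonical ordering => permutation invariance of the optimizer path
  ord <- do.call(order, c(unname(mf[gen_names]), list(mf$.y)))
  mf <- mf[ord, , drop = FALSE]
  fml <- stats::as.formula(paste(".y ~ 1 +",
                                 paste(sprintf("(1 | %s)", gen_names),
                                       collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = mf, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  vc <- lme4::VarCorr(fit)
  varcomp <- vapply(gen_names, function(g) as.numeric(vc[[g]]), numeric(1))
  names(varcomp) <- factors
  varcomp <- c(varcomp, residual = stats::sigma(fit)^2)
  varcomp[varcomp < 1e-10] <- 0
  re <- lme4::ranef(fit, condVar = FALSE)
  blup <- lapply(gen_names, function(g) {
    v <- re[[g]][["(Intercept)"]]
    names(v) <- rownames(re[[g]])
    v
  })
  names(blup) <- factors
  structure(list(varcomp = varcomp, blup = blup,
                 mu = unname(lme4::fixef(fit)[["(Intercept)"]]),
                 loglik = as.numeric(stats::logLik(fit)),
                 converged = converged, n = n, factors = factors,
                 response = response),
            class = "ranef_fit")
}

#' @export
print.ranef_fit <- function(x, ...) {
  cat("Random-effects model (REML), n =", x$n, "\n")
  cat("Variance components:\n")
  print(round(x$varcomp, 6))
  cat("Overall mean:", format(x$mu), "\n")
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' Pre-adjust plot records for design nuisance effects
#'
#' Removes the estimated overall mean and the BLUPs of the nuisance design
#' factors (trial, replicate, sub-block, and optionally time-point) from each
#' record, leaving the genotype signal plus residual:
#' `y* = y - mu - BLUP(trial) - BLUP(rep) - BLUP(subblock) [- BLUP(timepoint)]`.
#' The genotype BLUP is deliberately NOT subtracted; the adjusted record keeps
#' the genetic effect.
#'
#' @param data phenotype table.
#' @param nuisance character vector of nuisance factor terms (colon-joined for
#'   nesting); the genotype term is always added to the model itself.
#' @param include_timepoint add a crossed `timepoint` random effect (used for
#'   reflectance bands measured at several flights).
#' @param response name of the trait column.
#' @return `data` with an extra numeric column `adjusted` and the fitted
#'   `"ranef_fit"` attached as attribute `"fit"`.
#' @export
preadjust <- function(data, nuisance = c("trial", "trial:rep",
                                         "trial:rep:subblock"),
                      include_timepoint = FALSE, response = "value") {
  if (include_timepoint) nuisance <- c(nuisance, "timepoint")
  fit <- fit_random_model(data, factors = c("genotype", nuisance),
                          response = response)
  adj <- data[[response]] - fit$mu
  for (tm in nuisance) {
    lev <- as.character(term_factor(data, tm))
    b <- fit$blup[[tm]]
    adj <- adj - unname(b[lev])
  }
  out <- data
  out$adjusted <- adj
  attr(out, "fit") <- fit
  out
}

#' Pre-adjust a panel of band phenotypes
#'
#' Applies [preadjust()] band by band: each waveband is treated as the
#' response of its own random-effects model (genotype plus the nuisance
#' design factors, optionally a time-point effect) and the estimated mean and
#' nuisance BLUPs are subtracted. Plot records must be aligned between
#' `data` (which carries the design columns) and the rows of `X`.
#'
#' @param data phenotype table carrying the design columns of the plots.
#' @param X n x p matrix of band values, rows aligned with `data`.
#' @inheritParams preadjust
#' @return n x p matrix of adjusted band values.
#' @export
preadjust_bands <- function(data, X, nuisance = c("trial", "trial:rep",
                                                  "trial:rep:subblock"),
                            include_timepoint = FALSE) {
  X <- as.matrix(X)
  if (nrow(X) != nrow(data)) stop("X rows must align with the plot records")
  out <- X
  df <- data
  for (j in seq_len(ncol(X))) {
    df$value <- X[, j]
    out[, j] <- preadjust(df, nuisance = nuisance,
                          include_timepoint = include_timepoint)$adjusted
  }
  out
}

#' Outlier filtering and unit-variance standardization of adjusted records
#'
#' Flags records whose adjusted value lies beyond `fence` times the
#' inter-quartile range outside the 0.25/0.75 quantiles (linear-interpolation
#' quantiles, R type 7), then rescales the retained values to unit sample
#' variance. Use `fence = Inf` to disable the filter.
#'
#' @param adjusted numeric vector of pre-adjusted values (or a data frame with
#'   an `adjusted` column, as returned by [preadjust()]).
#' @param fence IQR multiplier of the outlier fence (default 3).
#' @return list with `retained` (logical flag per record), `values`
#'   (standardized values for retained records, `NA` elsewhere), `scale`
#'   (the sample SD divided out) and `bounds` (the fence).
#' @export
filter_standardize <- function(adjusted, fence = 3) {
  x <- if (is.data.frame(adjusted)) adjusted$adjusted else adjusted
  if (!is.numeric(x)) stop("adjusted values must be numeric")
  if (is.infinite(fence)) {
    retained <- !is.na(x)
    bounds <- c(-Inf, Inf)
  } else {
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    bounds <- c(q[1] - fence * iqr, q[2] + fence * iqr)
    retained <- !is.na(x) & x >= bounds[1] & x <= bounds[2]
  }
  if (sum(retained) < 4L) stop("fewer than 4 records retained after filtering")
  scale <- stats::sd(x[retained])
  if (!is.finite(scale) || scale <= 0)
    stop("zero variance after filtering; cannot standardize")
  values <- ifelse(retained, x / scale, NA_real_)
  list(retained = retained, values = values, scale = scale, bounds = bounds)
}

#' One-factor REML (genotype model)
#'
#' REML fit of `y_ij = mu + g_j + e_ij` with `g_j ~ iid N(0, s2g)` and
#' `e_ij ~ iid N(0, s2e)`, by profiling the restricted likelihood down to a
#' 1-D search over the variance ratio. This is the workhorse behind
#' heritability and sum-of-traits genetic covariance estimation; it operates
#' on group sufficient statistics and is therefore fast enough to be called
#' once per waveband and training partition.
#'
#' @param y numeric response vector.
#' @param group grouping (genotype) labels, same length as `y`.
#' @return list with `sigma2_g`, `sigma2_e`, `loglik` (restricted), `phi`
#'   (= s2g/s2e), `n` and `n_groups`.
#' @export
reml_onefactor <- function(y, group) {
  keep <- !is.na(y)
  y <- y[keep]
  g <- factor(as.character(group)[keep])
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations")
  if (nlevels(g) < 2L) stop("grouping factor has a single level")
  if (n <= nlevels(g)) stop("genotypes are not replicated; variance components are not identifiable")
  nj <- as.numeric(tabulate(g))
  s <- as.numeric(rowsum(y, g))
  yty <- sum(y * y)
  sst <- yty - sum(y)^2 / n
  ssw <- yty - sum(s^2 / nj)
  if (sst <= 0) {
    return(list(sigma2_g = 0, sigma2_e = 0, loglik = NA_real_, phi = NA_real_,
                n = n, n_groups = nlevels(g)))
  }
  if (ssw < 1e-12 * sst) {
    # all replicates identical within genotype: residual variance at boundary
    gm <- s / nj
    return(list(sigma2_g = stats::var(gm), sigma2_e = 0, loglik = Inf,
                phi = Inf, n = n, n_groups = nlevels(g)))
  }
  r <- cpp_reml1f(yty, s, nj, n)
  list(sigma2_g = r[1], sigma2_e = r[2], loglik = r[3], phi = r[4],
       n = n, n_groups = nlevels(g))
}

#' Plot-basis heritability
#'
#' Estimates `h2 = s2g / (s2g + s2e)` from the one-factor genotype model
#' fitted to (pre-adjusted, standardized) phenotypes, clipped to `[0, 1]`.
#'
#' @param y numeric phenotype vector.
#' @param genotype genotype labels.
#' @return heritability in `[0, 1]`, with the variance components attached as
#'   attribute `"varcomp"`.
#' @export
heritability <- function(y, genotype) {
  fit <- reml_onefactor(y, genotype)
  tot <- fit$sigma2_g + fit$sigma2_e
  if (tot <= 0) stop("both variance components are zero; heritability undefined")
  h2 <- min(max(fit$sigma2_g / tot, 0), 1)
  attr(h2, "varcomp") <- c(sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e)
  h2
}

#' Genetic covariance by the sum-of-traits identity
#'
#' Estimates the genetic covariance between two traits measured on the same
#' plots from three univariate one-factor REML fits:
#' `G = (s2g(y + x) - s2g(y) - s2g(x)) / 2`. Negative estimates (possible with
#' boundary-clipped components) are retained as-is.
#'
#' @param y,x numeric trait vectors on the same plots (same order).
#' @param genotype genotype labels.
#' @param keys_y,keys_x optional record keys; when both are given they must be
#'   identical, and the first mismatch is reported.
#' @return the estimated genetic covariance (scalar), with the three genetic
#'   variances attached as attribute `"components"`.
#' @export
gen_covariance <- function(y, x, genotype, keys_y = NULL, keys_x = NULL) {
  if (!is.null(keys_y) || !is.null(keys_x)) {
    if (is.null(keys_y) || is.null(keys_x) || length(keys_y) != length(keys_x))
      stop("record keys of y and x differ in length")
    bad <- which(as.character(keys_y) != as.character(keys_x))
    if (length(bad))
      stop("record keys mismatch at position ", bad[1], ": '",
           keys_y[bad[1]], "' vs '", keys_x[bad[1]], "'")
  }
  if (length(y) != length(x)) stop("y and x must have the same length")
  fy <- reml_onefactor(y, genotype)
  fx <- reml_onefactor(x, genotype)
  fs <- reml_onefactor(y + x, genotype)
  g <- 0.5 * (fs$sigma2_g - fy$sigma2_g - fx$sigma2_g)
  attr(g, "components") <- c(sigma2_g_y = fy$sigma2_g, sigma2_g_x = fx$sigma2_g,
                             sigma2_g_sum = fs$sigma2_g)
  g
}

#' Genetic covariances between a target trait and a panel of bands
#'
#' Applies the sum-of-traits identity band by band, sharing the grouping
#' sufficient statistics across the whole panel so that the p-band loop runs
#' in a single pass.
#'
#' @param y target trait vector (pre-adjusted, standardized).
#' @param X n x p matrix of band phenotypes on the same plots.
#' @param genotype genotype labels.
#' @return list with `G` (length-p named vector of genetic covariances),
#'   `sigma2_g_y`, `sigma2_g_x` (per band) and `sigma2_e_x` (per band).
#' @export
gen_covariance_panel <- function(y, X, genotype) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y must share plot records")
  g <- factor(as.character(genotype))
  n <- length(y)
  if (n <= nlevels(g)) stop("genotypes are not replicated")
  nj <- as.numeric(tabulate(g))
  sy <- as.numeric(rowsum(y, g))
  fy <- cpp_reml1f(sum(y * y), sy, nj, n)
  Sx <- rowsum(X, g)
  Ss <- Sx + sy
  yty_x <- colSums(X * X)
  yty_s <- yty_x + 2 * as.numeric(crossprod(X, y)) + sum(y * y)
  rx <- cpp_reml1f_multi(yty_x, Sx, nj, n)
  rs <- cpp_reml1f_multi(yty_s, Ss, nj, n)
  G <- 0.5 * (rs[1, ] - fy[1] - rx[1, ])
  names(G) <- colnames(X)
  list(G = G, sigma2_g_y = fy[1], sigma2_g_x = stats::setNames(rx[1, ], colnames(X)),
       sigma2_e_x = stats::setNames(rx[2, ], colnames(X)))
}
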