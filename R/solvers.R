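#' Phenotypic covariance matrix of a trait panel
#'
#' Unbiased sample covariance `X'X/(n-1)` of an n x p matrix of centered
#' (pre-adjusted, standardized) traits, symmetrized after computation.
#'
#' @param X numeric matrix, plots in rows, traits in columns.
#' @return symmetric p x p covariance matrix with the column labels of `X`.
#' @export
phen_cov <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows to estimate a covariance matrix")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  P <- crossprod(Xc) / (n - 1)
  (P + t(P)) / 2
}

check_cov_pair <- function(Px, Gxy) {
  Px <- as.matrix(Px)
  if (nrow(Px) != ncol(Px)) stop("Px must be square")
  if (max(abs(Px - t(Px))) > 1e-10) stop("Px is not symmetric")
  if (any(diag(Px) <= 0)) stop("Px has non-positive diagonal entries")
  if (length(Gxy) != nrow(Px)) stop("dimensions of Px and Gxy disagree")
  Px
}

new_psi <- function(beta, method, lambda = 0, alpha = NA_real_, q = NA_integer_,
                    labels = NULL) {
  beta <- as.numeric(beta)
  if (!is.null(labels)) names(beta) <- labels
  structure(list(beta = beta, method = method, lambda = lambda, alpha = alpha,
                 q = q, active = which(beta != 0), labels = labels),
            class = "psi")
}

#' Standard (Smith-Hazel type) selection index
#'
#' Solves `Px beta = Gxy`, the first-order condition of minimizing the expected
#' squared deviation between the index `x'beta` and the genetic merit of the
#' target. Requires a well-conditioned phenotypic covariance matrix; for
#' singular or near-singular `Px` use one of the regularized indices instead.
#'
#' @param Px p x p phenotypic covariance matrix of the measured traits.
#' @param Gxy length-p vector of genetic covariances between the measured
#'   traits and the target.
#' @return object of class `"psi"` with the index weights in `$beta`.
#' @export
standard_si <- function(Px, Gxy) {
  Px <- check_cov_pair(Px, Gxy)
  rc <- rcond(Px)
  if (!is.finite(rc) || rc < 1e-12)
    stop("Px is singular or ill-conditioned (rcond = ", format(rc),
         "); use an L2-, L1- or PC-regularized index instead")
  beta <- solve(Px, as.numeric(Gxy))
  res <- sqrt(sum((Px %*% beta - Gxy)^2))
  if (res > 1e-8 * max(sqrt(sum(Gxy^2)), 1e-300) && any(Gxy != 0))
    stop("linear solve did not reach the requested residual accuracy")
  new_psi(beta, "standard", lambda = 0,
          labels = colnames(Px) %||% names(Gxy))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' L2-penalized (ridge-type) selection index
#'
#' Closed-form solution `beta = (Px + lambda I)^{-1} Gxy`; `lambda = 0`
#' recovers the standard index.
#'
#' @inheritParams standard_si
#' @param lambda non-negative ridge penalty.
#' @return object of class `"psi"`.
#' @export
l2_psi <- function(Px, Gxy, lambda) {
  Px <- check_cov_pair(Px, Gxy)
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single non-negative number")
  A <- Px + diag(lambda, nrow(Px))
  if (rcond(A) < 1e-14)
    stop("Px + lambda*I is singular; increase lambda")
  beta <- solve(A, as.numeric(Gxy))
  new_psi(beta, "L2", lambda = lambda, alpha = 0,
          labels = colnames(Px) %||% names(Gxy))
}

#' Default penalty grid for L1/elastic-net indices
#'
#' Log-spaced decreasing grid from `lambda_max = max|Gxy| / max(alpha, 1e-3)`
#' (the smallest penalty with an all-zero L1 solution) down to
#' `min_ratio * lambda_max`.
#'
#' @param Gxy genetic covariance vector.
#' @param alpha elastic-net mixing parameter.
#' @param nlambda number of grid points.
#' @param min_ratio ratio of the smallest to the largest grid value.
#' @return decreasing numeric vector of penalties.
#' @export
si_lambda_grid <- function(Gxy, alpha = 1, nlambda = 100, min_ratio = 1e-4) {
  lmax <- max(abs(Gxy)) / max(alpha, 1e-3)
  if (lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Elastic-net / L1 penalized selection index (coordinate descent)
#'
#' Minimizes the covariance-form objective
#' `-Gxy'beta + beta'Px beta/2 + lambda * ((1-alpha)/2 ||beta||_2^2 + alpha ||beta||_1)`
#' by cyclical coordinate descent with covariance updates, warm-started along a
#' decreasing penalty grid. `alpha = 1` gives the LASSO-type sparse index,
#' `alpha = 0` the ridge-type index.
#'
#' @inheritParams standard_si
#' @param lambda decreasing vector of penalties; default [si_lambda_grid()].
#' @param alpha elastic-net mixing parameter in `[0, 1]`.
#' @param tol convergence threshold on the largest absolute coefficient change
#'   in a full sweep.
#' @param maxit maximum number of sweeps per penalty value.
#' @param beta_start optional warm-start coefficients.
#' @return object of class `"psi_path"`: coefficients (p x nlambda), penalties,
#'   active-set sizes, and per-penalty convergence flags.
#' @export
en_psi <- function(Px, Gxy, lambda = NULL, alpha = 1,
                   tol = 1e-9, maxit = 10000L, beta_start = NULL) {
  Px <- check_cov_pair(Px, Gxy)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single number in [0, 1]")
  if (is.null(lambda)) lambda <- si_lambda_grid(Gxy, alpha)
  lambda <- as.numeric(lambda)
  if (any(diff(lambda) >= 0)) {
    if (length(lambda) > 1L) stop("lambda grid must be strictly decreasing")
  }
  if (any(lambda < 0)) stop("lambda values must be non-negative")
  fit <- cpp_cd_enet(Px, as.numeric(Gxy), lambda, alpha,
                     tol, as.integer(maxit), beta_start)
  if (!all(fit$converged))
    warning("coordinate descent did not converge at ",
            sum(!fit$converged), " penalty value(s)")
  labels <- colnames(Px) %||% names(Gxy)
  if (!is.null(labels)) rownames(fit$beta) <- labels
  structure(list(beta = fit$beta, lambda = lambda, alpha = alpha,
                 method = if (alpha == 1) "L1" else if (alpha == 0) "L2" else "EN",
                 type = "grid", n_active = colSums(fit$beta != 0),
                 converged = fit$converged, iter = fit$iter, labels = labels),
            class = "psi_path")
}

#' L1 selection-index path by covariance-form LARS
#'
#' Computes the full piecewise-linear LASSO (`alpha = 1`) solution path with
#' the lasso modification (coefficients crossing zero are dropped), entirely
#' from `Px` and `Gxy` ("covariance updates"); no data matrix is needed.
#' Ties at entry events are broken by lowest band index and counted in
#' attribute `"ties"`.
#'
#' @inheritParams standard_si
#' @param max_steps safety cap on the number of path events.
#' @return object of class `"psi_path"` with `type = "lars"`: knot penalties
#'   (decreasing, first knot `lambda_max` with the zero solution) and knot
#'   coefficients; [coef.psi_path()] interpolates exactly between knots.
#' @export
lars_psi <- function(Px, Gxy, max_steps = NULL) {
  Px <- check_cov_pair(Px, Gxy)
  G <- as.numeric(Gxy)
  p <- length(G)
  if (is.null(max_steps)) max_steps <- 8L * p + 10L
  tol <- 1e-12
  beta <- numeric(p)
  cc <- G
  lam <- max(abs(cc))
  knots_l <- lam
  knots_b <- matrix(beta, ncol = 1)
  actions <- character(0)
  ties <- 0L
  if (lam <= tol) {
    out <- list(beta = knots_b, lambda = knots_l, alpha = 1, method = "L1",
                type = "lars", labels = colnames(Px) %||% names(Gxy),
                actions = actions)
    attr(out, "ties") <- ties
    return(structure(out, class = "psi_path"))
  }
  A <- integer(0)
  sA <- numeric(0)
  dropped_j <- NA_integer_
  dropped_lam <- NA_real_
  step <- 0L
  while (lam > tol && step < max_steps) {
    step <- step + 1L
    # bands whose correlation is at the boundary enter (exact ties are
    # processed one per pass, lowest band index first)
    inact_now <- setdiff(seq_len(p), A)
    at_bound <- inact_now[abs(cc[inact_now]) >= lam - 1e-9 * max(lam, 1)]
    if (!is.na(dropped_j) && abs(lam - dropped_lam) <= 1e-12 * max(lam, 1))
      at_bound <- setdiff(at_bound, dropped_j)  # lasso drop: no instant re-entry
    if (length(at_bound)) {
      if (length(at_bound) > 1L) ties <- ties + 1L
      for (jnew in sort(at_bound)) {   # exact ties enter together, low index first
        A <- c(A, jnew)
        sA <- c(sA, sign(cc[jnew]))
        actions <- c(actions, paste0("enter:", jnew))
      }
    }
    if (!length(A)) break
    PAA <- Px[A, A, drop = FALSE]
    if (rcond(PAA) < 1e-12) break  # path cannot proceed past rank
    w <- solve(PAA, sA)
    # inactive entry events: c_j(l) = c_j - (lam - l) * a_j hits +-l
    inact <- setdiff(seq_len(p), A)
    lam_ev <- 0
    ev_type <- "end"
    ev_j <- NA_integer_
    if (length(inact)) {
      a <- as.numeric(Px[inact, A, drop = FALSE] %*% w)
      l_plus <- (cc[inact] - lam * a) / (1 - a)
      l_minus <- (lam * a - cc[inact]) / (1 + a)
      for (k in seq_along(inact)) {
        for (lcand in c(l_plus[k], l_minus[k])) {
          if (is.finite(lcand) && lcand > tol && lcand < lam - 1e-9 * max(lam, 1)) {
            if (lcand > lam_ev + tol) {
              lam_ev <- lcand; ev_type <- "enter"; ev_j <- inact[k]
            } else if (abs(lcand - lam_ev) <= tol && ev_type == "enter" &&
                       inact[k] < ev_j) {
              ties <- ties + 1L
              ev_j <- inact[k]
            }
          }
        }
      }
    }
    # drop events: beta_j(l) = beta_j + (lam - l) w_j crosses zero
    ld <- lam + beta[A] / w
    for (k in seq_along(A)) {
      lcand <- ld[k]
      if (is.finite(lcand) && lcand > tol && lcand < lam - 1e-9 * max(lam, 1)) {
        if (lcand > lam_ev + tol) {
          lam_ev <- lcand; ev_type <- "drop"; ev_j <- A[k]
        } else if (abs(lcand - lam_ev) <= tol && ev_type == "drop" &&
                   ev_j > A[k]) {
          ties <- ties + 1L
          ev_j <- A[k]
        }
      }
    }
    lam_new <- if (ev_type == "end") 0 else lam_ev
    beta[A] <- beta[A] + (lam - lam_new) * w
    lam <- lam_new
    cc <- G - as.numeric(Px %*% beta)
    if (ev_type == "drop") {
      beta[ev_j] <- 0
      keep <- A != ev_j
      A <- A[keep]
      sA <- sA[keep]
      actions <- c(actions, paste0("drop:", ev_j))
      dropped_j <- ev_j
      dropped_lam <- lam
    }
    knots_l <- c(knots_l, lam)
    knots_b <- cbind(knots_b, beta)
    if (ev_type == "end") break
  }
  labels <- colnames(Px) %||% names(Gxy)
  if (!is.null(labels)) rownames(knots_b) <- labels
  out <- list(beta = knots_b, lambda = knots_l, alpha = 1, method = "L1",
              type = "lars", n_active = colSums(knots_b != 0),
              labels = labels, actions = actions)
  attr(out, "ties") <- ties
  structure(out, class = "psi_path")
}

#' Singular value decomposition of a trait matrix
#'
#' Thin SVD `X = U D V'` of the (column-centered) trait matrix, the basis of
#' the reduced-rank index. Principal-component scores are `W = X V = U D`.
#'
#' @param X n x p trait matrix.
#' @param center center columns on their means before decomposing.
#' @return object of class `"spectral"`: list with `u`, `d`, `v`, `n`,
#'   `center` (column means used) and column labels.
#' @export
spectral <- function(X, center = TRUE) {
  X <- as.matrix(X)
  cm <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2L, cm, "-")
  sv <- svd(Xc)
  structure(list(u = sv$u, d = sv$d, v = sv$v, n = nrow(X), center = cm,
                 labels = colnames(X)),
            class = "spectral")
}

#' Principal-component scores from a spectral decomposition
#'
#' @param decomp a `"spectral"` object.
#' @param q number of leading components.
#' @return n x q matrix of PC scores `W = U D`.
#' @export
pc_scores <- function(decomp, q = length(decomp$d)) {
  stopifnot(inherits(decomp, "spectral"))
  decomp$u[, seq_len(q), drop = FALSE] %*%
    diag(decomp$d[seq_len(q)], q)
}

#' Reduced-rank (principal-component) selection index
#'
#' Regresses the genetic merit on the top `q` PC scores. Because `W'W = D^2`,
#' the method-of-moments phenotypic covariance of the scores is diagonal,
#' `D^2/(n-1)`, so the PC coefficients are
#' `gamma = (n-1) D^{-2} G_wy` and the trait-space weights are
#' `beta = (n-1) V_q D^{-2} G_wy`. With `q = p` (full rank) this reproduces
#' the standard index built from `X'X/(n-1)`.
#'
#' @param decomp `"spectral"` decomposition of the (centered) trait matrix.
#' @param G_wy genetic covariances between the leading PC scores and the
#'   target (length at least `q`); typically estimated on the scores with
#'   [gen_covariance_panel()], or rotated from band-level covariances via
#'   [rotate_gencov()].
#' @param q number of components to use.
#' @return object of class `"psi"` with trait-space weights; the PC-space
#'   coefficients are attached as attribute `"gamma"`.
#' @export
pc_si <- function(decomp, G_wy, q) {
  stopifnot(inherits(decomp, "spectral"))
  d <- decomp$d
  rank <- sum(d > 1e-10 * d[1])
  if (q < 1L || q > rank)
    stop("q = ", q, " exceeds the numerical rank of the trait matrix (rank = ",
         rank, ")")
  if (length(G_wy) < q) stop("G_wy must supply at least q entries")
  n <- decomp$n
  gamma <- (n - 1) * G_wy[seq_len(q)] / d[seq_len(q)]^2
  beta <- as.numeric(decomp$v[, seq_len(q), drop = FALSE] %*% gamma)
  out <- new_psi(beta, "PC", lambda = 0, q = as.integer(q),
                 labels = decomp$labels)
  attr(out, "gamma") <- gamma
  out
}

#' Rotate band-level genetic covariances to PC space
#'
#' `G_wy = V' Gxy`: the genetic covariances of the PC scores with the target
#' implied by band-level covariances.
#'
#' @param decomp `"spectral"` object.
#' @param Gxy band-level genetic covariance vector.
#' @return vector of PC-level genetic covariances.
#' @export
rotate_gencov <- function(decomp, Gxy) {
  stopifnot(inherits(decomp, "spectral"))
  as.numeric(crossprod(decomp$v, as.numeric(Gxy)))
}

#' Evaluate a selection index on new trait records
#'
#' `I = X beta`. When both the coefficients and `X` carry band labels they
#' must match exactly.
#'
#' @param X m x p matrix of trait records.
#' @param coef a `"psi"` object or bare numeric weight vector.
#' @return numeric vector of index values, one per row of `X`.
#' @export
compute_index <- function(X, coef) {
  beta <- if (inherits(coef, "psi")) coef$beta else as.numeric(coef)
  X <- as.matrix(X)
  if (ncol(X) != length(beta))
    stop("X has ", ncol(X), " columns but the index has ", length(beta),
         " coefficients")
  if (!is.null(colnames(X)) && !is.null(names(beta))) {
    bad <- which(colnames(X) != names(beta))
    if (length(bad))
      stop("band labels disagree: ",
           paste(sprintf("'%s' vs '%s'", colnames(X)[utils::head(bad, 5)],
                         names(beta)[utils::head(bad, 5)]), collapse = ", "))
  }
  as.numeric(X %*% beta)
}

#' Karush-Kuhn-Tucker residual of an L1/elastic-net index solution
#'
#' Largest violation of the stationarity conditions of the covariance-form
#' elastic-net objective: for active bands
#' `Gxy_j - (Px beta)_j = lambda*alpha*sign(beta_j) + lambda*(1-alpha)*beta_j`,
#' for inactive bands `|Gxy_j - (Px beta)_j| <= lambda*alpha`. A small value
#' certifies optimality without reference to any particular solver.
#'
#' @inheritParams standard_si
#' @param beta coefficient vector to certify.
#' @param lambda,alpha penalty at which `beta` was computed.
#' @return the largest violation (non-negative scalar).
#' @export
kkt_violation <- function(Px, Gxy, beta, lambda, alpha = 1) {
  r <- as.numeric(Gxy) - as.numeric(Px %*% beta)
  act <- beta != 0
  v <- 0
  if (any(act))
    v <- max(abs(r[act] - lambda * alpha * sign(beta[act]) -
                   lambda * (1 - alpha) * beta[act]))
  if (any(!act))
    v <- max(v, max(pmax(abs(r[!act]) - lambda * alpha, 0)))
  v
}

# --- S3 surface -------------------------------------------------------------

#' Fit a selection index
#'
#' Front end to the index solvers. Depending on `method`, weights are computed
#' from the phenotypic covariance matrix `Px` and the genetic covariance
#' vector `Gxy` (standard, L2, L1, EN) or from a spectral decomposition of the
#' trait matrix plus PC-level genetic covariances (PC).
#'
#' @param Px phenotypic covariance matrix (not used for `method = "PC"`).
#' @param Gxy genetic covariance vector (band level).
#' @param method one of `"standard"`, `"L2"`, `"L1"`, `"EN"`, `"PC"`.
#' @param lambda penalty (scalar for L2; decreasing grid or `NULL` for L1/EN).
#' @param alpha elastic-net mixing parameter (EN only; L1 fixes 1, L2 fixes 0).
#' @param q number of components (PC only).
#' @param decomp `"spectral"` object (PC only).
#' @param G_wy PC-level genetic covariances (PC only); defaults to
#'   `rotate_gencov(decomp, Gxy)` when `Gxy` is given.
#' @param ... passed to the underlying solver.
#' @return a `"psi"` object (single solution) or `"psi_path"` (L1/EN grid).
#' @seealso [standard_si()], [l2_psi()], [en_psi()], [lars_psi()], [pc_si()]
#' @export
psi <- function(Px = NULL, Gxy = NULL,
                method = c("standard", "L2", "L1", "EN", "PC"),
                lambda = NULL, alpha = NULL, q = NULL,
                decomp = NULL, G_wy = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    standard = standard_si(Px, Gxy),
    L2 = {
      if (is.null(lambda)) stop("method 'L2' needs a scalar lambda")
      l2_psi(Px, Gxy, lambda)
    },
    L1 = en_psi(Px, Gxy, lambda = lambda, alpha = 1, ...),
    EN = en_psi(Px, Gxy, lambda = lambda,
                alpha = if (is.null(alpha)) 0.5 else alpha, ...),
    PC = {
      if (is.null(decomp)) stop("method 'PC' needs a spectral decomposition")
      if (is.null(q)) stop("method 'PC' needs the number of components q")
      if (is.null(G_wy)) {
        if (is.null(Gxy)) stop("supply G_wy or band-level Gxy")
        G_wy <- rotate_gencov(decomp, Gxy)
      }
      pc_si(decomp, G_wy, q)
    })
}

#' @export
print.psi <- function(x, ...) {
  cat("Selection index (", x$method, ")\n", sep = "")
  cat("  bands: ", length(x$beta), ", active: ", length(x$active), "\n", sep = "")
  if (x$method %in% c("L1", "L2", "EN"))
    cat("  lambda: ", format(x$lambda),
        if (is.finite(x$alpha)) paste0(", alpha: ", format(x$alpha)), "\n",
        sep = "")
  if (x$method == "PC") cat("  components: ", x$q, "\n", sep = "")
  invisible(x)
}

#' @export
coef.psi <- function(object, ...) object$beta

#' @export
summary.psi <- function(object, ...) {
  cat("Selection index (", object$method, ")\n", sep = "")
  cat("  p = ", length(object$beta), ", active = ", length(object$active),
      "\n", sep = "")
  cat("  ||beta||_1 = ", format(sum(abs(object$beta))),
      ", ||beta||_2 = ", format(sqrt(sum(object$beta^2))), "\n", sep = "")
  invisible(object)
}

#' @export
predict.psi <- function(object, newdata, ...) compute_index(newdata, object)

#' @export
plot.psi <- function(x, ...) {
  graphics::plot(seq_along(x$beta), x$beta, type = "h",
                 xlab = "band", ylab = "coefficient",
                 main = paste0("Selection index (", x$method, ")"), ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Extract coefficients from an index path
#'
#' For coordinate-descent grid paths, returns the solution at a stored grid
#' penalty (matched within a relative tolerance of 1e-8). For LARS paths the
#' solution is piecewise linear in the penalty and is interpolated exactly at
#' any `lambda` between 0 and `lambda_max`; above `lambda_max` the solution
#' is zero.
#'
#' @param object a `"psi_path"`.
#' @param lambda penalty value(s) at which to evaluate; `NULL` returns the
#'   whole coefficient matrix (p x n_lambda).
#' @param ... unused.
#' @return coefficient vector (single `lambda`) or matrix.
#' @export
coef.psi_path <- function(object, lambda = NULL, ...) {
  if (is.null(lambda)) return(object$beta)
  sapply(lambda, function(l) {
    if (object$type == "lars") {
      kl <- object$lambda
      if (l >= kl[1]) return(object$beta[, 1])
      if (l < kl[length(kl)] - 1e-12)
        stop("lambda below the end of the computed path (",
             format(kl[length(kl)]), ")")
      i <- max(which(kl >= l - 1e-12))
      if (i == length(kl)) return(object$beta[, i])
      gap <- kl[i] - kl[i + 1]
      if (gap <= 1e-15) return(object$beta[, i + 1])
      w <- (kl[i] - l) / gap
      (1 - w) * object$beta[, i] + w * object$beta[, i + 1]
    } else {
      i <- which(abs(object$lambda - l) <= 1e-8 * max(l, 1e-300))
      if (!length(i)) stop("lambda = ", format(l), " is not on the stored grid")
      object$beta[, i[1]]
    }
  })
}

#' @export
print.psi_path <- function(x, ...) {
  cat("Selection index path (", x$method,
      if (x$type == "lars") ", LARS knots" else ", coordinate descent",
      ")\n", sep = "")
  cat("  p = ", nrow(x$beta), ", penalties = ", length(x$lambda),
      ", lambda in [", format(min(x$lambda)), ", ", format(max(x$lambda)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
plot.psi_path <- function(x, ...) {
  ll <- log10(pmax(x$lambda, 1e-12))
  graphics::matplot(ll, t(x$beta), type = "l", lty = 1,
                    xlab = "log10(lambda)", ylab = "coefficient",
                    main = paste0(x$method, " selection-index path"), ...)
  invisible(x)
}
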