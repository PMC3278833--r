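#' Build the lagged regression design of an MVAR(1) model
#'
#' Stacks the time series into the standard regression form `Y = Z beta + E`
#' with `T - 1` aligned rows: row `t` of `Y` holds the expression vector at
#' time `t + 1` and row `t` of `Z` the vector one step before. No centering
#' or scaling is applied; synthetic series are generated without an
#' intercept on a common scale (use [scale()] beforehand for real data if
#' per-gene centering is wanted).
#'
#' @param data Expression matrix, genes in rows, `T >= 2` time points in
#'   columns.
#' @return A list of class `mvar_design` with `(T-1) x I` matrices `Y` and
#'   `Z`.
#' @export
build_design <- function(data) {
  if (!is.matrix(data)) stop("`data` must be a matrix", call. = FALSE)
  if (ncol(data) < 2L)
    stop("at least 2 time points are required", call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` must be finite", call. = FALSE)
  xt <- t(data)
  structure(list(Y = xt[-1L, , drop = FALSE],
                 Z = xt[-nrow(xt), , drop = FALSE],
                 gene_labels = rownames(data)),
            class = "mvar_design")
}

new_mvar_model <- function(beta_hat, penalty, lambda, alpha, dof,
                           resid_sigma2, cv_error = NULL, n_obs,
                           rank_deficient = FALSE) {
  lab <- colnames(beta_hat)
  nm <- function(x) if (is.null(x)) x else setNames(unname(x), lab)
  structure(list(beta_hat = beta_hat, penalty = penalty,
                 lambda = nm(lambda), alpha = nm(alpha), dof = nm(dof),
                 resid_sigma2 = nm(resid_sigma2), cv_error = nm(cv_error),
                 n_obs = n_obs, rank_deficient = rank_deficient),
            class = "mvar_model")
}

#' @export
coef.mvar_model <- function(object, ...) object$beta_hat

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("MVAR(1) model: %d genes, penalty = %s, %d design rows\n",
              ncol(x$beta_hat), x$penalty, x$n_obs))
  if (x$penalty != "ols")
    cat(sprintf("  lambda: [%.4g, %.4g], alpha: [%.3g, %.3g]\n",
                min(x$lambda), max(x$lambda), min(x$alpha), max(x$alpha)))
  cat(sprintf("  nonzero coefficients: %d of %d\n",
              sum(x$beta_hat != 0), length(x$beta_hat)))
  invisible(x)
}

# Coordinate descent leaves numerically-zero coefficients (warm-start
# residue ~1e-16); zero them so the support, dof and significance
# machinery see exact zeros.
zap_tiny <- function(beta_hat) {
  tiny <- 1e-10 * max(1, max(abs(beta_hat)))
  beta_hat[abs(beta_hat) < tiny] <- 0
  beta_hat
}

# Per-target residual variance: RSS / (n - d) with d capped at n - 1 and
# the estimate floored at machine epsilon.
resid_sigma2_of <- function(design, beta_hat, dof) {
  n <- nrow(design$Z)
  R <- design$Y - design$Z %*% beta_hat
  rss <- colSums(R^2)
  d <- pmin(dof, n - 1L)
  pmax(rss / (n - d), .Machine$double.eps)
}

#' Ordinary least-squares MVAR(1) estimate
#'
#' `beta_hat = (Z'Z)^{-1} Z'Y`. Requires more design rows than genes for a
#' unique solution; on a rank-deficient design the minimum-norm solution is
#' returned via the pseudo-inverse with a warning, and the model is flagged.
#'
#' @param design An [build_design()] result.
#' @return An `mvar_model`.
#' @export
fit_ols <- function(design) {
  stopifnot(inherits(design, "mvar_design"))
  Z <- design$Z
  n <- nrow(Z); p <- ncol(Z)
  qz <- qr(Z)
  rank_deficient <- qz$rank < p
  if (rank_deficient) {
    warning("design is rank deficient; returning the minimum-norm ",
            "least-squares solution", call. = FALSE)
    beta_hat <- MASS::ginv(Z) %*% design$Y
  } else {
    beta_hat <- qr.coef(qz, design$Y)
  }
  dimnames(beta_hat) <- list(design$gene_labels, design$gene_labels)
  dof <- rep(qz$rank, p)
  new_mvar_model(beta_hat, penalty = "ols",
                 lambda = rep(0, p), alpha = rep(NA_real_, p), dof = dof,
                 resid_sigma2 = resid_sigma2_of(design, beta_hat, dof),
                 n_obs = n, rank_deficient = rank_deficient)
}

# log-spaced lambda path from lambda_max down, glmnet-style.
lambda_path <- function(Z, y, alpha, nlambda = 100L, min_ratio = NULL) {
  n <- nrow(Z)
  if (is.null(min_ratio)) min_ratio <- if (n < ncol(Z)) 0.01 else 1e-4
  lmax <- max(abs(crossprod(Z, y))) / (n * max(alpha, 1e-3))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

ridge_solve <- function(Z, Y, lambda_eff) {
  p <- ncol(Z)
  solve(crossprod(Z) + diag(lambda_eff, p), crossprod(Z, Y))
}

#' Fit a penalized MVAR(1) model at fixed penalty parameters
#'
#' Minimizes, independently for each target gene `j`,
#' `(1/(2n)) ||Y_j - Z b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)`.
#' Ridge (`alpha = 0`) is solved in closed form as
#' `(Z'Z + n lambda I)^{-1} Z'Y`; lasso (`alpha = 1`) and elastic-net are
#' solved by cyclic coordinate descent to a relative objective tolerance of
#' `1e-7`. `lambda = 0` reduces to [fit_ols()].
#'
#' @param design An [build_design()] result.
#' @param penalty One of `"ridge"`, `"lasso"`, `"enet"`.
#' @param lambda Penalty weight (>= 0), a scalar or one value per target
#'   gene.
#' @param alpha Elastic-net mixing in `[0, 1]`; implied 0 for ridge and 1
#'   for lasso.
#' @param tol,maxit Coordinate-descent convergence controls.
#' @return An `mvar_model`.
#' @export
fit_penalized <- function(design, penalty = c("ridge", "lasso", "enet"),
                          lambda, alpha = NULL, tol = 1e-7, maxit = 100000L) {
  stopifnot(inherits(design, "mvar_design"))
  penalty <- match.arg(penalty)
  alpha <- switch(penalty,
    ridge = 0,
    lasso = 1,
    enet = {
      if (is.null(alpha) || !is.numeric(alpha) || alpha < 0 || alpha > 1)
        stop("`alpha` must be in [0, 1] for the elastic-net", call. = FALSE)
      alpha
    })
  Z <- design$Z; Y <- design$Y
  n <- nrow(Z); p <- ncol(Z)
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("`lambda` must be non-negative", call. = FALSE)
  lambda <- rep(lambda, length.out = p)

  beta_hat <- matrix(0, p, p, dimnames = list(design$gene_labels,
                                              design$gene_labels))
  for (lam in unique(lambda)) {
    j <- which(lambda == lam)
    if (lam == 0) {
      beta_hat[, j] <- suppressWarnings(fit_ols(design))$beta_hat[, j]
    } else if (alpha == 0) {
      beta_hat[, j] <- ridge_solve(Z, Y[, j, drop = FALSE], n * lam)
    } else {
      for (jj in j) {
        fit <- cd_enet_path_cpp(Z, Y[, jj], lam, alpha, tol, maxit,
                                warm = FALSE)
        beta_hat[, jj] <- fit$beta[, 1L]
      }
    }
  }
  beta_hat <- zap_tiny(beta_hat)
  dof <- colSums(beta_hat != 0)
  new_mvar_model(beta_hat, penalty = penalty, lambda = lambda,
                 alpha = rep(alpha, p), dof = dof,
                 resid_sigma2 = resid_sigma2_of(design, beta_hat, dof),
                 n_obs = n)
}

#' Tune and fit a penalized MVAR(1) model by leave-one-out cross-validation
#'
#' For every candidate penalty configuration, each design row is held out
#' in turn, the model is refit on the remaining rows, and the squared
#' prediction error on the held-out row is accumulated; the configuration
#' minimizing the total error is selected per target gene and the final
#' model refit on all rows. Ridge uses the exact hat-matrix shortcut over
#' the grid `{0.001, 0.1, 1, 10, 100}` (effective penalty `n * lambda` held
#' fixed across folds, which keeps the shortcut exact); lasso and
#' elastic-net refit explicitly over the solution-path grid of 100
#' log-spaced lambda values generated from the data, the elastic-net
#' additionally over the alpha grid `{0.1, ..., 0.9}`. Ties are broken
#' toward the smallest lambda, then the smallest alpha.
#'
#' The penalty weight lambda is always tuned per target gene (the
#' multivariate problem decomposes column-wise). The elastic-net mixing
#' alpha is, by default, selected once for the whole network as the value
#' minimizing the LOOCV error summed over all target regressions
#' (`alpha_tuning = "shared"`); per-target alpha selection is available
#' with `alpha_tuning = "per_target"`.
#'
#' @param data Expression matrix, genes in rows, `T >= 3` time points in
#'   columns.
#' @param penalty One of `"ridge"`, `"lasso"`, `"enet"`.
#' @param lambda_grid Optional lambda grid; defaults to
#'   `c(0.001, 0.1, 1, 10, 100)` for ridge and to the per-target solution
#'   path for lasso/elastic-net.
#' @param alpha_grid Elastic-net mixing grid; default `seq(0.1, 0.9, 0.1)`.
#' @param alpha_tuning `"shared"` (one alpha per network, default) or
#'   `"per_target"`.
#' @param nlambda,lambda_min_ratio Solution-path controls for lasso and
#'   elastic-net.
#' @param tol,maxit Coordinate-descent convergence controls.
#' @return An `mvar_model` with per-target `lambda`, `alpha`, degrees of
#'   freedom (nonzero-coefficient count), residual variance and CV error.
#' @export
#' @examples
#' net <- generate_scale_free(6, seed = 1)
#' beta <- sample_coefficients(net, seed = 2)
#' x <- simulate_timeseries(beta, 20, seed = 3)
#' fit <- loocv_tune(x, "lasso")
#' fit
loocv_tune <- function(data, penalty = c("ridge", "lasso", "enet"),
                       lambda_grid = NULL, alpha_grid = NULL,
                       alpha_tuning = c("shared", "per_target"),
                       nlambda = 100L, lambda_min_ratio = NULL,
                       tol = 1e-7, maxit = 100000L) {
  alpha_tuning <- match.arg(alpha_tuning)
  penalty <- match.arg(penalty)
  design <- build_design(data)
  Z <- design$Z; Y <- design$Y
  n <- nrow(Z); p <- ncol(Z)
  if (n < 2L)
    stop("leave-one-out tuning needs at least 3 time points", call. = FALSE)
  if (!is.null(lambda_grid) && length(lambda_grid) == 0L)
    stop("`lambda_grid` must be non-empty", call. = FALSE)
  if (!is.null(alpha_grid) && length(alpha_grid) == 0L)
    stop("`alpha_grid` must be non-empty", call. = FALSE)

  if (penalty == "ridge") {
    grid <- if (is.null(lambda_grid)) c(0.001, 0.1, 1, 10, 100) else
      lambda_grid
    cv <- matrix(NA_real_, length(grid), p)
    for (g in seq_along(grid)) {
      A <- crossprod(Z) + diag(n * grid[g], p)
      M <- solve(A, t(Z))              # p x n
      h <- colSums(t(Z) * M)           # leverage of each row
      R <- Y - Z %*% (M %*% Y)
      cv[g, ] <- colMeans((R / pmax(1 - h, 1e-10))^2)
    }
    sel <- vapply(seq_len(p), function(j) {
      cand <- which(cv[, j] == min(cv[, j]))
      cand[which.min(grid[cand])]
    }, integer(1L))
    lambda_sel <- grid[sel]
    beta_hat <- matrix(0, p, p)
    for (lam in unique(lambda_sel)) {
      j <- which(lambda_sel == lam)
      beta_hat[, j] <- ridge_solve(Z, Y[, j, drop = FALSE], n * lam)
    }
    alpha_sel <- rep(0, p)
    cv_min <- cv[cbind(sel, seq_len(p))]
  } else {
    alphas <- if (penalty == "lasso") 1 else {
      if (is.null(alpha_grid)) seq(0.1, 0.9, by = 0.1) else alpha_grid
    }
    # per-(alpha, target): LOOCV over the lambda path, ties -> smallest
    # lambda
    cells <- vector("list", length(alphas))
    for (ai in seq_along(alphas)) {
      a <- alphas[ai]
      cells[[ai]] <- lapply(seq_len(p), function(j) {
        lams <- if (is.null(lambda_grid))
          lambda_path(Z, Y[, j], a, nlambda, lambda_min_ratio) else
          sort(lambda_grid, decreasing = TRUE)
        cv <- cd_enet_loocv_cpp(Z, Y[, j], lams, a, tol, maxit)
        cand <- which(cv == min(cv))
        k <- cand[which.min(lams[cand])]
        list(cv = cv[k], lambda = lams[k], k = k, lams = lams)
      })
    }
    if (alpha_tuning == "shared" || length(alphas) == 1L) {
      tot <- vapply(cells, function(cl)
        sum(vapply(cl, `[[`, 0, "cv")), 0)
      cand <- which(tot == min(tot))
      alpha_idx <- rep(cand[which.min(alphas[cand])], p)
    } else {
      alpha_idx <- vapply(seq_len(p), function(j) {
        cvj <- vapply(cells, function(cl) cl[[j]]$cv, 0)
        lamj <- vapply(cells, function(cl) cl[[j]]$lambda, 0)
        cand <- which(cvj == min(cvj))
        cand <- cand[lamj[cand] == min(lamj[cand])]
        cand[which.min(alphas[cand])]
      }, integer(1L))
    }
    beta_hat <- matrix(0, p, p)
    lambda_sel <- alpha_sel <- cv_min <- numeric(p)
    for (j in seq_len(p)) {
      best <- cells[[alpha_idx[j]]][[j]]
      a <- alphas[alpha_idx[j]]
      path <- cd_enet_path_cpp(Z, Y[, j], best$lams[seq_len(best$k)], a,
                               tol, maxit, warm = TRUE)
      beta_hat[, j] <- path$beta[, best$k]
      lambda_sel[j] <- best$lambda
      alpha_sel[j] <- a
      cv_min[j] <- best$cv
    }
  }
  dimnames(beta_hat) <- list(design$gene_labels, design$gene_labels)
  beta_hat <- zap_tiny(beta_hat)
  dof <- colSums(beta_hat != 0)
  new_mvar_model(beta_hat, penalty = penalty, lambda = lambda_sel,
                 alpha = alpha_sel, dof = dof,
                 resid_sigma2 = resid_sigma2_of(design, beta_hat, dof),
                 cv_error = cv_min, n_obs = n)
}
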