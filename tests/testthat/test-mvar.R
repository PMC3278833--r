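test_that("the regression design aligns responses with lagged predictors", {
  x <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("G", 1:3), c("t0", "t1")))
  d <- build_design(x)
  expect_equal(dim(d$Y), c(1L, 3L))
  expect_equal(drop(d$Z), x[, 1], ignore_attr = TRUE)
  expect_equal(drop(d$Y), x[, 2], ignore_attr = TRUE)
  x10 <- matrix(rnorm(40), 4, 10)
  expect_equal(nrow(build_design(x10)$Y), 9L)
  # noiseless series satisfy Y = Z beta exactly
  beta <- sample_coefficients(generate_scale_free(6, seed = 1), seed = 2)
  xs <- simulate_timeseries(beta, 12, innovation_cov = 0, seed = 3)
  ds <- build_design(xs)
  expect_equal(ds$Y, ds$Z %*% beta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(build_design(xs[, 1, drop = FALSE]), "2 time points")
})

test_that("least squares recovers noiseless coefficients and matches a QR
           oracle", {
  beta <- sample_coefficients(generate_scale_free(6, seed = 4), seed = 5)
  diag(beta) <- seq(0.2, 0.7, length.out = 6)
  x <- simulate_timeseries(beta, 40, innovation_cov = 0, seed = 6)
  fit <- fit_ols(build_design(x))
  expect_lt(max(abs(fit$beta_hat - beta)), 1e-8)
  # scalar AR(1)
  z <- matrix(rnorm(20), 20, 1)
  xs <- rbind(t(z), t(z * 0.5))  # not a real series; build design manually
  d <- structure(list(Y = z * 0.5, Z = z, gene_labels = "G1"),
                 class = "mvar_design")
  expect_equal(unname(drop(fit_ols(d)$beta_hat)), 0.5, tolerance = 1e-12)
  # random multi-target design vs qr.solve
  withr::with_seed(7, {
    Z <- matrix(rnorm(100), 20, 5)
    Y <- matrix(rnorm(100), 20, 5)
  })
  d2 <- structure(list(Y = Y, Z = Z, gene_labels = paste0("G", 1:5)),
                  class = "mvar_design")
  expect_lt(max(abs(fit_ols(d2)$beta_hat - qr.solve(Z, Y))), 1e-10)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  withr::with_seed(8, {
    Z <- matrix(rnorm(30), 10, 3)
    Z <- cbind(Z, Z[, 1])          # duplicated predictor
    Y <- matrix(rnorm(40), 10, 4)
  })
  d <- structure(list(Y = Y, Z = Z, gene_labels = paste0("G", 1:4)),
                 class = "mvar_design")
  expect_warning(fit <- fit_ols(d), "rank deficient")
  expect_true(fit$rank_deficient)
  expect_true(all(is.finite(fit$beta_hat)))
})

make_design <- function(n, p, seed, beta = NULL, sd = 1) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p)
    if (is.null(beta)) beta <- matrix(rnorm(p * p), p, p)
    Y <- Z %*% beta + matrix(rnorm(n * p, sd = sd), n, p)
  })
  structure(list(Y = Y, Z = Z, gene_labels = paste0("G", seq_len(p))),
            class = "mvar_design")
}

test_that("penalized fits obey the closed-form limits", {
  d <- make_design(30, 6, seed = 9)
  ols <- fit_ols(d)
  for (pen in c("ridge", "lasso", "enet")) {
    f0 <- fit_penalized(d, pen, lambda = 0, alpha = 0.5)
    expect_lt(max(abs(f0$beta_hat - ols$beta_hat)), 1e-8)
    fbig <- fit_penalized(d, pen, lambda = 1e8, alpha = 0.5)
    expect_lt(max(abs(fbig$beta_hat)), 1e-6)
  }
  expect_error(fit_penalized(d, "lasso", lambda = -1), "non-negative")
  # ridge on orthonormal predictors: beta_ols / (1 + n * lambda)
  withr::with_seed(10, {
    Z <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
    Y <- matrix(rnorm(40 * 5), 40, 5)
  })
  do <- structure(list(Y = Y, Z = Z, gene_labels = paste0("G", 1:5)),
                  class = "mvar_design")
  lam <- 0.3
  fr <- fit_penalized(do, "ridge", lambda = lam)
  expect_equal(fr$beta_hat, fit_ols(do)$beta_hat / (1 + nrow(Z) * lam),
               tolerance = 1e-8)
})

test_that("coordinate descent solutions satisfy the subgradient optimality
           conditions and beat random perturbations", {
  d <- make_design(30, 8, seed = 11)
  lam <- 0.1
  for (alpha in c(1, 0.5)) {
    fit <- fit_penalized(d, if (alpha == 1) "lasso" else "enet",
                         lambda = lam, alpha = alpha, tol = 1e-12)
    for (j in c(1, 4, 8)) {
      b <- fit$beta_hat[, j]
      y <- d$Y[, j]
      expect_lt(kkt_violation(d$Z, y, b, lam, alpha), 1e-6)
      obj <- enet_objective(d$Z, y, b, lam, alpha)
      perturbed <- withr::with_seed(12, vapply(1:200, function(r)
        enet_objective(d$Z, y, b + rnorm(8, sd = 0.05), lam, alpha), 0))
      expect_true(all(obj <= perturbed + 1e-5))
    }
  }
})

test_that("the coordinate-descent path matches glmnet", {
  skip_if_not_installed("glmnet")
  d <- make_design(40, 10, seed = 13)
  # unit-variance response: glmnet rescales the L2 penalty by the response
  # standard deviation internally, so the objectives coincide only there
  y <- d$Y[, 3]
  y <- y / sqrt(mean((y - mean(y))^2))
  for (alpha in c(1, 0.5)) {
    g <- glmnet::glmnet(d$Z, y, alpha = alpha, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14)
    lams <- g$lambda
    ours <- grnstab:::cd_enet_path_cpp(d$Z, y, lams, alpha, 1e-12, 1e6, TRUE)
    expect_lt(max(abs(ours$beta - as.matrix(g$beta))), 1e-4)
  }
})

test_that("warm-started paths agree with cold restarts and the elastic-net
           interpolates between lasso and ridge", {
  d <- make_design(35, 9, seed = 14)
  y <- d$Y[, 1]
  lams <- grnstab:::lambda_path(d$Z, y, 1)
  warm <- grnstab:::cd_enet_path_cpp(d$Z, y, lams, 1, 1e-12, 1e6, TRUE)
  cold <- grnstab:::cd_enet_path_cpp(d$Z, y, lams, 1, 1e-12, 1e6, FALSE)
  expect_lt(max(abs(warm$beta - cold$beta)), 1e-5)
  # alpha = 1 equals the lasso solver exactly
  f1 <- fit_penalized(d, "enet", lambda = 0.2, alpha = 1)
  fl <- fit_penalized(d, "lasso", lambda = 0.2)
  expect_equal(f1$beta_hat, fl$beta_hat)
  # alpha -> 0 approaches closed-form ridge
  fe <- fit_penalized(d, "enet", lambda = 0.3, alpha = 1e-4, tol = 1e-12)
  frr <- fit_penalized(d, "ridge", lambda = 0.3)
  expect_lt(max(abs(fe$beta_hat - frr$beta_hat)), 1e-4)
})

test_that("lasso support sizes never exceed min(design rows, genes)", {
  beta <- stationary_truth(12, seed = 15)
  x <- simulate_timeseries(beta, 9, seed = 16)   # 8 design rows, 12 genes
  fit <- loocv_tune(x, "lasso")
  expect_true(all(fit$dof <= min(8, 12)))
  x2 <- simulate_timeseries(beta, 30, seed = 17)
  fit2 <- loocv_tune(x2, "lasso")
  expect_true(all(fit2$dof <= 12))
})

test_that("leave-one-out tuning selects sensibly across grids", {
  beta <- stationary_truth(8, seed = 18)
  x <- simulate_timeseries(beta, 25, seed = 19)
  # a single-candidate grid is returned as-is
  f1 <- loocv_tune(x, "lasso", lambda_grid = 0.37)
  expect_true(all(f1$lambda == 0.37))
  f2 <- loocv_tune(x, "ridge", lambda_grid = 2.5)
  expect_true(all(f2$lambda == 2.5))
  expect_error(loocv_tune(x, "lasso", lambda_grid = numeric(0)), "non-empty")
  expect_error(loocv_tune(x, "enet", alpha_grid = numeric(0)), "non-empty")
  # with many rows and tiny noise the smallest ridge penalty wins
  xs <- simulate_timeseries(stationary_truth(8, self = 0.4, seed = 20),
                            300, innovation_cov = 1e-6, seed = 21)
  fr <- loocv_tune(xs, "ridge")
  expect_true(all(fr$lambda == 0.001))
})

test_that("tuned lasso recovers the exact support of a persistently
           excited sparse system", {
  beta <- stationary_truth(10, seed = 2)
  truth <- (beta != 0) * 1L
  x <- simulate_timeseries(beta, 400, seed = 4)
  fit <- loocv_tune(x, "lasso")
  # every true edge is picked up by the tuned fit
  expect_true(all(fit$beta_hat[truth == 1] != 0))
  # and the stringent significance rule returns exactly the truth
  net <- suppressWarnings(
    significant_edges(fit, build_design(x), level = 1e-4))
  expect_equal(unname(net), unname(truth))
})

test_that("shared-alpha elastic-net tuning reports one mixing value", {
  beta <- stationary_truth(6, seed = 22)
  x <- simulate_timeseries(beta, 25, seed = 23)
  fs <- loocv_tune(x, "enet", alpha_grid = c(0.3, 0.6, 0.9))
  expect_equal(length(unique(fs$alpha)), 1L)
  expect_true(unique(fs$alpha) %in% c(0.3, 0.6, 0.9))
  fp <- loocv_tune(x, "enet", alpha_grid = c(0.3, 0.6, 0.9),
                   alpha_tuning = "per_target")
  expect_true(all(fp$alpha %in% c(0.3, 0.6, 0.9)))
})
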