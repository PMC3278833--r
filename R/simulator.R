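#' Sample ground-truth MVAR coefficients on a topology
#'
#' Draws the nonzero coefficients of a first-order MVAR model on a given
#' support: entries on edges have magnitude uniform on `[low, high]` and
#' signs assigned so that the numbers of positive and negative coefficients
#' differ by at most one; entries off the support are exactly zero.
#'
#' @param support Binary connectivity matrix (row = regulator, column =
#'   target).
#' @param low,high Magnitude range, `0 < low < high`. Defaults 0.8 and 1.
#' @param seed Optional integer seed.
#' @return A numeric coefficient matrix `beta` with the same dimnames;
#'   `beta[i, j]` is the effect of gene `i` at time `t - 1` on gene `j` at
#'   time `t`.
#' @export
#' @examples
#' net <- generate_scale_free(10, seed = 1)
#' beta <- sample_coefficients(net, seed = 2)
#' range(abs(beta[net == 1]))
sample_coefficients <- function(support, low = 0.8, high = 1.0, seed = NULL) {
  support <- check_connectivity(support)
  if (!is.numeric(low) || !is.numeric(high) || low <= 0 || low >= high)
    stop("need 0 < low < high", call. = FALSE)
  beta <- matrix(0, nrow(support), ncol(support),
                 dimnames = dimnames(support))
  idx <- which(support == 1L)
  ne <- length(idx)
  if (ne == 0L) return(beta)
  with_seed(seed, {
    mag <- runif(ne, low, high)
    signs <- rep(c(1, -1), length.out = ne)
    signs <- sample(signs)
    beta[idx] <- mag * signs
  })
  beta
}

#' Simulate an MVAR(1) gene-expression time series
#'
#' Generates `x(t)` for `t = 1, ..., n_timepoints` from the first-order
#' model `y^t = y^{t-1} beta + eps^t` (row-vector form), with the initial
#' expression vector drawn uniformly on `[init_low, init_high]` and i.i.d.
#' Gaussian innovations with covariance `innovation_cov` (identity by
#' default, the setting of the synthetic study).
#'
#' @param beta `I x I` coefficient matrix (row = regulator, column =
#'   target).
#' @param n_timepoints Number of time points `T >= 2`.
#' @param init_low,init_high Range of the uniform initial expressions
#'   (defaults 10 and 15).
#' @param innovation_cov Innovation covariance: a scalar variance (applied
#'   to all genes), a length-`I` diagonal, or a full symmetric positive
#'   semi-definite `I x I` matrix. Default 1 (identity covariance). Use 0
#'   for noiseless dynamics.
#' @param seed Optional integer seed.
#' @return An `I x n_timepoints` expression matrix, genes in rows, time
#'   points in columns (labelled `t0, t1, ...`).
#' @export
#' @examples
#' net <- generate_scale_free(10, seed = 1)
#' beta <- sample_coefficients(net, seed = 2)
#' x <- simulate_timeseries(beta, 30, seed = 3)
#' dim(x)
simulate_timeseries <- function(beta, n_timepoints, init_low = 10,
                                init_high = 15, innovation_cov = 1,
                                seed = NULL) {
  if (!is.matrix(beta) || nrow(beta) != ncol(beta))
    stop("`beta` must be a square matrix", call. = FALSE)
  n_timepoints <- as.integer(n_timepoints)
  if (is.na(n_timepoints) || n_timepoints < 2L)
    stop("`n_timepoints` must be at least 2", call. = FALSE)
  if (init_low > init_high)
    stop("`init_low` must not exceed `init_high`", call. = FALSE)
  I <- nrow(beta)
  chol_sigma <- innovation_chol(innovation_cov, I)

  labels <- rownames(beta)
  if (is.null(labels)) labels <- default_gene_labels(I)
  x <- matrix(0, I, n_timepoints,
              dimnames = list(labels, paste0("t", seq_len(n_timepoints) - 1L)))
  tb <- t(beta)
  with_seed(seed, {
    x[, 1L] <- runif(I, init_low, init_high)
    for (t in 2L:n_timepoints) {
      eps <- if (is.null(chol_sigma)) numeric(I) else
        drop(crossprod(chol_sigma, rnorm(I)))
      x[, t] <- drop(tb %*% x[, t - 1L]) + eps
    }
  })
  if (!all(is.finite(x)))
    stop("simulated trajectory overflowed; check that `beta` is stable",
         call. = FALSE)
  x
}

# Upper-triangular Cholesky factor of the innovation covariance, or NULL
# for an exactly-zero covariance.
innovation_chol <- function(innovation_cov, I) {
  if (is.matrix(innovation_cov)) {
    if (!identical(dim(innovation_cov), c(I, I)) ||
        !isSymmetric(unname(innovation_cov), tol = 1e-8))
      stop("`innovation_cov` must be a symmetric I x I matrix",
           call. = FALSE)
    sigma <- innovation_cov
  } else if (is.numeric(innovation_cov) &&
             length(innovation_cov) %in% c(1L, I)) {
    if (any(innovation_cov < 0))
      stop("`innovation_cov` variances must be non-negative", call. = FALSE)
    sigma <- diag(rep(innovation_cov, length.out = I), I)
  } else {
    stop("`innovation_cov` must be a scalar, length-I vector, or I x I matrix",
         call. = FALSE)
  }
  if (all(sigma == 0)) return(NULL)
  ch <- tryCatch(chol(sigma, pivot = FALSE), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values)))
      stop("`innovation_cov` must be positive semi-definite", call. = FALSE)
    v <- pmax(ev$values, 0)
    ch <- diag(sqrt(v), length(v)) %*% t(ev$vectors)
  }
  ch
}

#' Add Gaussian perturbation noise to an expression matrix
#'
#' Adds i.i.d. Gaussian noise with standard deviation `sigma + delta` to
#' every entry: the perturbation model `N(0, (sigma + delta)^2)` where
#' `sigma` is the residual standard deviation of the unperturbed data and
#' `delta` a perturbation constant.
#'
#' @param data Expression matrix (genes x time points).
#' @param sigma Residual standard deviation of the data.
#' @param delta Perturbation constant; `sigma + delta` must be >= 0.
#'   `delta = -sigma` returns the input unchanged.
#' @param seed Optional integer seed.
#' @return A perturbed matrix of the same shape and labels.
#' @export
perturb <- function(data, sigma, delta = 0, seed = NULL) {
  if (!is.matrix(data)) stop("`data` must be a matrix", call. = FALSE)
  sdev <- sigma + delta
  if (!is.finite(sdev) || sdev < 0)
    stop("`sigma + delta` must be non-negative", call. = FALSE)
  if (sdev == 0) return(data)
  with_seed(seed, data + matrix(rnorm(length(data), 0, sdev),
                                nrow(data), ncol(data)))
}

#' Perturbation constant for a target signal-to-noise ratio
#'
#' The signal-to-noise ratio of a perturbation is defined as
#' `SNR = Var(signal) / (sigma + delta)^2`, with `Var(signal)` the overall
#' sample variance of the unperturbed matrix. Given a target SNR this
#' returns the `delta` achieving it: `sigma + delta =
#' sqrt(Var(signal)/SNR)`. A target of `Inf` gives `delta = -sigma`
#' (zero perturbation).
#'
#' @param target_snr Desired signal-to-noise ratio (> 0; `Inf` allowed).
#' @param signal_variance Overall sample variance of the data (> 0).
#' @param sigma Residual standard deviation of the data (>= 0).
#' @return The perturbation constant `delta`.
#' @seealso [perturbation_snr()] for the forward direction.
#' @export
#' @examples
#' delta_for_snr(4, signal_variance = 1, sigma = 0) # 0.5
delta_for_snr <- function(target_snr, signal_variance, sigma) {
  if (!is.numeric(target_snr) || target_snr <= 0)
    stop("`target_snr` must be positive", call. = FALSE)
  if (!is.numeric(signal_variance) || signal_variance <= 0)
    stop("`signal_variance` must be positive", call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("`sigma` must be non-negative", call. = FALSE)
  if (is.infinite(target_snr)) return(-sigma)
  sqrt(signal_variance / target_snr) - sigma
}

#' Signal-to-noise ratio of a perturbation
#'
#' @inheritParams delta_for_snr
#' @param delta Perturbation constant; `sigma + delta` must be > 0.
#' @return `signal_variance / (sigma + delta)^2`.
#' @export
perturbation_snr <- function(signal_variance, sigma, delta) {
  sdev <- sigma + delta
  if (sdev < 0) stop("`sigma + delta` must be non-negative", call. = FALSE)
  if (sdev == 0) return(Inf)
  signal_variance / sdev^2
}
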