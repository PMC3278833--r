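test_that("coefficients live on the support with balanced signs", {
  empty <- matrix(0L, 4, 4)
  expect_true(all(sample_coefficients(empty, seed = 1) == 0))
  for (s in 1:5) {
    net <- generate_scale_free(10, seed = s)
    beta <- sample_coefficients(net, seed = 50 + s)
    expect_equal(beta != 0, net == 1, ignore_attr = TRUE)
    mags <- abs(beta[net == 1])
    expect_true(all(mags >= 0.8 & mags <= 1))
    npos <- sum(beta > 0)
    expect_true(npos %in% c(4L, 5L))
  }
  expect_error(sample_coefficients(generate_scale_free(3, seed = 1),
                                   low = 1, high = 0.5), "low < high")
})

test_that("coefficient magnitudes are uniform on [low, high]", {
  support <- matrix(1L, 101, 101)
  diag(support) <- 0L
  beta <- sample_coefficients(support, seed = 9)
  mags <- abs(beta[beta != 0])
  expect_gte(length(mags), 1e4)
  ks <- suppressWarnings(ks.test(mags, "punif", 0.8, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated dynamics follow the lag-1 recursion", {
  # zero dynamics, zero noise: everything after t0 is exactly 0
  x <- simulate_timeseries(matrix(0, 3, 3), 6, innovation_cov = 0, seed = 1)
  expect_true(all(x[, -1] == 0))
  expect_true(all(x[, 1] >= 10 & x[, 1] <= 15))
  # identity dynamics: the initial state is a fixed point
  x <- simulate_timeseries(diag(3), 6, innovation_cov = 0, seed = 2)
  expect_equal(x, x[, c(1, 1, 1, 1, 1, 1)], ignore_attr = TRUE)
  # exact recursion with known innovations suppressed
  beta <- sample_coefficients(generate_scale_free(5, seed = 3), seed = 4)
  x <- simulate_timeseries(beta, 8, innovation_cov = 0, seed = 5)
  for (t in 2:8)
    expect_equal(x[, t], drop(t(beta) %*% x[, t - 1]), ignore_attr = TRUE)
  # determinism
  expect_identical(simulate_timeseries(beta, 10, seed = 6),
                   simulate_timeseries(beta, 10, seed = 6))
  expect_error(simulate_timeseries(beta, 1), "at least 2")
  expect_error(simulate_timeseries(beta, 5,
                                   innovation_cov = matrix(-1, 5, 5)),
               "symmetric|semi-definite")
})

test_that("innovation variance is recovered from long simulations", {
  beta <- sample_coefficients(generate_scale_free(10, seed = 11), seed = 12)
  x <- simulate_timeseries(beta, 5000, seed = 13)
  expect_true(all(is.finite(x)))
  fit <- fit_ols(build_design(x))
  expect_true(all(abs(fit$resid_sigma2 - 1) < 0.05))
  expect_lt(max(abs(fit$beta_hat - beta)), 0.1)
})

test_that("trajectories on acyclic supports stay bounded over long runs", {
  beta <- sample_coefficients(generate_scale_free(10, seed = 21), seed = 22)
  x <- simulate_timeseries(beta, 1e4, seed = 23)
  expect_true(all(is.finite(x)))
})

test_that("perturbation adds Gaussian noise of sd sigma + delta", {
  x <- simulate_timeseries(sample_coefficients(
    generate_scale_free(91, seed = 31), seed = 32), 48, seed = 33)
  expect_identical(perturb(x, sigma = 0.3, delta = -0.3, seed = 1), x)
  p1 <- perturb(x, sigma = 0.225, delta = 0, seed = 34)
  expect_identical(dim(p1), dim(x))
  expect_lt(abs(sd(p1 - x) - 0.225) / 0.225, 0.03)
  expect_identical(perturb(x, 0.225, 0, seed = 34),
                   perturb(x, 0.225, 0, seed = 34))
  expect_error(perturb(x, sigma = 0.1, delta = -0.2), "non-negative")
})

test_that("stronger perturbation increases the expected squared change", {
  x <- matrix(0, 10, 10)
  msd <- function(delta) {
    mean(vapply(1:100, function(r)
      mean((perturb(x, sigma = 0.5, delta = delta, seed = r) - x)^2), 0))
  }
  expect_gt(msd(1.5), msd(0.5))
})

test_that("delta_for_snr inverts the signal-to-noise definition", {
  expect_equal(delta_for_snr(4, signal_variance = 1, sigma = 0), 0.5)
  expect_equal(delta_for_snr(1, signal_variance = 1, sigma = 1), 0)
  expect_equal(delta_for_snr(Inf, signal_variance = 2, sigma = 0.3), -0.3)
  snrs <- withr::with_seed(41, runif(20, 0.01, 4))
  for (s in snrs) {
    d <- delta_for_snr(s, signal_variance = 2.7, sigma = 0.4)
    expect_equal(perturbation_snr(2.7, 0.4, d), s, tolerance = 1e-12)
  }
  expect_error(delta_for_snr(0, 1, 1), "positive")
  expect_error(delta_for_snr(1, -1, 1), "positive")
  expect_error(delta_for_snr(1, 1, -1), "non-negative")
})
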