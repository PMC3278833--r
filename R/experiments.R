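#' Configuration of a synthetic replicate benchmark
#'
#' Bundles every parameter controlling the simulation study: network sizes,
#' series lengths, replicate count, methods, topology and coefficient
#' sampling parameters, detection cutoff, tuning grids and the master seed.
#' The defaults are the study conditions of the benchmark: sizes
#' `{10, 50, 100}`, lengths `{10, 30, 50, 70}`, `B = 100` replicates,
#' attachment power 1.2, coefficient magnitudes in `[0.8, 1]`, initial
#' expressions in `[10, 15]`, identity innovation covariance, detection
#' cutoff `1e-4`, ridge grid `{0.001, 0.1, 1, 10, 100}` and elastic-net
#' alpha grid `{0.1, ..., 0.9}`.
#'
#' @param n_genes Integer vector of network sizes.
#' @param timepoints Integer vector of series lengths.
#' @param n_replicates Number of replicate datasets per cell (`B >= 2`).
#' @param methods Subset of `c("lasso", "enet", "ridge")`.
#' @param attachment An [attachment_params()] object.
#' @param coef_range Magnitude range of true coefficients.
#' @param init_range Range of uniform initial expressions.
#' @param innovation_cov Innovation covariance passed to
#'   [simulate_timeseries()].
#' @param epsilon Edge-detection cutoff.
#' @param sparse_edges How lasso/elastic-net coefficient matrices are read
#'   as networks in the benchmark: `"significance"` (default) keeps the
#'   support coefficients with a two-sided t p-value below `sig_level`
#'   (see [significant_edges()]); `"cutoff"` keeps every coefficient with
#'   `|beta| > epsilon`. Ridge always uses the plain cutoff (its dense
#'   estimate is reported unfiltered).
#' @param sig_level Per-coefficient significance level for
#'   `sparse_edges = "significance"`.
#' @param ridge_lambda_grid Ridge tuning grid.
#' @param enet_alpha_grid Elastic-net mixing grid.
#' @param snr_grid Signal-to-noise grid for perturbation studies.
#' @param master_seed Integer master seed; every topology, coefficient
#'   draw and replicate seed is derived from it with [derive_seed()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_genes = c(10L, 50L, 100L),
                              timepoints = c(10L, 30L, 50L, 70L),
                              n_replicates = 100L,
                              methods = c("lasso", "enet", "ridge"),
                              attachment = attachment_params(),
                              coef_range = c(0.8, 1),
                              init_range = c(10, 15),
                              innovation_cov = 1,
                              epsilon = 1e-4,
                              sparse_edges = c("significance", "cutoff"),
                              sig_level = 0.05,
                              ridge_lambda_grid = c(0.001, 0.1, 1, 10, 100),
                              enet_alpha_grid = seq(0.1, 0.9, by = 0.1),
                              snr_grid = c(0.01, 0.1, 0.5, 1, 2, 4),
                              master_seed = 1L) {
  methods <- match.arg(methods, c("lasso", "enet", "ridge"),
                       several.ok = TRUE)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 2L)
    stop("`n_replicates` must be at least 2", call. = FALSE)
  if (length(n_genes) == 0L || length(timepoints) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  if (epsilon < 0) stop("`epsilon` must be non-negative", call. = FALSE)
  sparse_edges <- match.arg(sparse_edges)
  if (!is.numeric(sig_level) || sig_level <= 0 || sig_level >= 1)
    stop("`sig_level` must be in (0, 1)", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 timepoints = as.integer(timepoints),
                 n_replicates = n_replicates, methods = methods,
                 attachment = attachment, coef_range = coef_range,
                 init_range = init_range, innovation_cov = innovation_cov,
                 epsilon = epsilon, sparse_edges = sparse_edges,
                 sig_level = sig_level,
                 ridge_lambda_grid = ridge_lambda_grid,
                 enet_alpha_grid = enet_alpha_grid, snr_grid = snr_grid,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

fit_method <- function(data, method, config) {
  switch(method,
    ridge = loocv_tune(data, "ridge",
                       lambda_grid = config$ridge_lambda_grid),
    lasso = loocv_tune(data, "lasso"),
    enet = loocv_tune(data, "enet", alpha_grid = config$enet_alpha_grid))
}

#' Run the synthetic replicate benchmark
#'
#' For every (network size, series length) cell: one scale-free topology
#' and one coefficient matrix are generated from the master seed, `B`
#' replicate time series are simulated by redrawing the initial expressions
#' and innovations, each series is tuned by leave-one-out cross-validation
#' and fitted with each requested method, the fitted coefficient matrix is
#' read as a network (magnitude cutoff for ridge; significant support
#' coefficients for lasso/elastic-net, see [experiment_config()]),
#' accuracy is scored against the generating network, and the overall
#' stability of the `B` detected networks is computed.
#' All methods within a cell are fitted on the same replicate series, so
#' method comparisons are paired. Replicates whose fit fails are excluded
#' from the averages and counted in `n_failed`.
#'
#' @param config An [experiment_config()].
#' @param keep_networks If `TRUE`, the detected networks and the
#'   ground-truth topology of every cell are attached as the
#'   `"cell_details"` attribute.
#' @param verbose Print progress per cell.
#' @return A data frame with one row per (size, length, method):
#'   `n_genes`, `n_timepoints`, `method`, `mean_tp`, `mean_fp`,
#'   `mean_precision`, `mean_recall`, `mean_f`, `stability`, `n_failed`.
#'   Per-cell edge-stability matrices are attached as the
#'   `"edge_stability"` attribute (for histogramming the edge-frequency
#'   distributions).
#' @export
#' @examples
#' cfg <- experiment_config(n_genes = 10, timepoints = 10, n_replicates = 5,
#'                          methods = "ridge", master_seed = 7)
#' run_synthetic_benchmark(cfg)
run_synthetic_benchmark <- function(config, keep_networks = FALSE,
                                    verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  rows <- list()
  edge_stab <- list()
  details <- list()
  B <- config$n_replicates
  for (I in config$n_genes) {
    for (T in config$timepoints) {
      cell_seed <- derive_seed(config$master_seed, I, T)
      truth <- generate_scale_free(I, config$attachment,
                                   seed = derive_seed(cell_seed, 1L))
      beta <- sample_coefficients(truth, config$coef_range[1L],
                                  config$coef_range[2L],
                                  seed = derive_seed(cell_seed, 2L))
      nets <- rep(list(vector("list", B)), length(config$methods))
      names(nets) <- config$methods
      acc <- list()
      failed <- integer(length(config$methods))
      names(failed) <- config$methods
      for (b in seq_len(B)) {
        data <- simulate_timeseries(beta, T, config$init_range[1L],
                                    config$init_range[2L],
                                    config$innovation_cov,
                                    seed = derive_seed(cell_seed, 2L + b))
        for (method in config$methods) {
          net <- tryCatch({
            fit <- fit_method(data, method, config)
            if (method == "ridge" || config$sparse_edges == "cutoff")
              detect_edges(fit, config$epsilon)
            else
              suppressWarnings(significant_edges(
                fit, build_design(data), level = config$sig_level,
                epsilon = config$epsilon))
          }, error = function(e) NULL)
          if (is.null(net)) {
            failed[method] <- failed[method] + 1L
            next
          }
          nets[[method]][[b]] <- net
          acc[[method]][[length(acc[[method]]) + 1L]] <-
            network_accuracy(net, truth)
        }
      }
      for (method in config$methods) {
        ok_nets <- Filter(Negate(is.null), nets[[method]])
        a <- acc[[method]]
        stab <- if (length(ok_nets) >= 2L) overall_stability(ok_nets) else
          NULL
        key <- sprintf("%d_%d_%s", I, T, method)
        edge_stab[[key]] <- if (!is.null(stab)) stab$edge_stability else
          NULL
        if (keep_networks)
          details[[key]] <- list(truth = truth, beta = beta,
                                 networks = ok_nets)
        rows[[key]] <- data.frame(
          n_genes = I, n_timepoints = T, method = method,
          mean_tp = mean(vapply(a, `[[`, 0, "tp")),
          mean_fp = mean(vapply(a, `[[`, 0, "fp")),
          mean_precision = mean(vapply(a, `[[`, 0, "precision")),
          mean_recall = mean(vapply(a, `[[`, 0, "recall")),
          mean_f = mean(vapply(a, `[[`, 0, "f_measure")),
          stability = if (!is.null(stab)) stab$overall else NA_real_,
          n_failed = failed[[method]],
          stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf(
            "I=%d T=%d %s: F=%.2f recall=%.2f stability=%.2f",
            I, T, method, rows[[key]]$mean_f, rows[[key]]$mean_recall,
            rows[[key]]$stability))
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "edge_stability") <- edge_stab
  if (keep_networks) attr(out, "cell_details") <- details
  out
}

#' Noise-perturbation stability study
#'
#' Fits the unperturbed data once and takes its statistically significant
#' edges (t-based p-values with Benjamini–Hochberg control at level `q`) as
#' the reference network, then, for each signal-to-noise ratio in
#' `snr_grid`, generates `B` perturbed datasets by adding Gaussian noise of
#' standard deviation `sigma + delta` (with `delta` chosen by
#' [delta_for_snr()] and `sigma` the residual standard deviation of the
#' reference fit), refits each, takes the significant edges, and records
#' the overall stability of the `B` networks, the per-edge stability, the
#' consensus network of edges with frequency > `threshold`, and the
#' F-measure against the reference network (the network inferred on the
#' unperturbed data is treated as the truth).
#'
#' @param data Expression matrix, genes in rows, `T >= 3` time points in
#'   columns.
#' @param method `"lasso"` or `"enet"` (ridge allowed but not
#'   recommended).
#' @param snr_grid Positive signal-to-noise ratios; `Inf` expresses the
#'   zero-perturbation limit.
#' @param n_replicates Perturbed datasets per SNR (`B >= 2`).
#' @param q FDR level for edge significance.
#' @param threshold Consensus-edge frequency threshold.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param config An [experiment_config()] supplying tuning grids.
#' @return A list of class `perturbation_study` with `summary` (data frame:
#'   `snr`, `delta`, `stability`, `f_measure`, `n_failed`),
#'   `stable_networks` (one consensus matrix per SNR), `edge_stability`
#'   (one frequency matrix per SNR) and `reference` (model, network and
#'   residual `sigma` of the unperturbed fit).
#' @export
run_perturbation_study <- function(data, method = c("lasso", "enet", "ridge"),
                                   snr_grid = c(0.01, 0.1, 0.5, 1, 2, 4),
                                   n_replicates = 100L, q = 0.05,
                                   threshold = 0.5, seed = 1L,
                                   config = experiment_config()) {
  method <- match.arg(method)
  if (!is.matrix(data) || ncol(data) < 3L)
    stop("`data` must be a matrix with at least 3 time points",
         call. = FALSE)
  if (any(snr_grid <= 0)) stop("SNR values must be positive", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2L)
    stop("`n_replicates` must be at least 2", call. = FALSE)

  ref_model <- fit_method(data, method, config)
  ref_design <- build_design(data)
  ref_sig <- coefficient_pvalues(ref_model, ref_design, q)
  ref_net <- ref_sig$significant
  resid <- ref_design$Y - ref_design$Z %*% ref_model$beta_hat
  sigma <- sd(as.vector(resid))
  signal_var <- var(as.vector(data))

  summary_rows <- list()
  stable_nets <- list()
  edge_stabs <- list()
  for (s in seq_along(snr_grid)) {
    snr <- snr_grid[s]
    delta <- delta_for_snr(snr, signal_var, sigma)
    nets <- list()
    failed <- 0L
    for (b in seq_len(n_replicates)) {
      pdata <- perturb(data, sigma, delta,
                       seed = derive_seed(seed, s, b))
      net <- tryCatch({
        fit <- fit_method(pdata, method, config)
        coefficient_pvalues(fit, build_design(pdata), q)$significant
      }, error = function(e) NULL)
      if (is.null(net)) failed <- failed + 1L else
        nets[[length(nets) + 1L]] <- net
    }
    stab <- overall_stability(nets)
    cons <- stable_network(nets, threshold)
    key <- as.character(snr)
    stable_nets[[key]] <- cons
    edge_stabs[[key]] <- stab$edge_stability
    f <- mean(vapply(nets, function(n)
      network_accuracy(n, ref_net)$f_measure, 0))
    summary_rows[[key]] <- data.frame(snr = snr, delta = delta,
                                      stability = stab$overall,
                                      f_measure = f, n_failed = failed)
  }
  structure(list(summary = do.call(rbind, c(summary_rows,
                                            make.row.names = FALSE)),
                 stable_networks = stable_nets,
                 edge_stability = edge_stabs,
                 reference = list(model = ref_model, network = ref_net,
                                  sigma = sigma,
                                  signal_variance = signal_var)),
            class = "perturbation_study")
}
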