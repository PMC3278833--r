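#' Pairwise Hamming-based stability of two networks
#'
#' Similarity of two binary networks inferred on replicate data:
#' `rho(a, b) = 1 - d_H(a, b) / (|a| + |b|)`, where `d_H` counts entries
#' where the connectivity matrices differ (both spurious and missing edges)
#' and `|.|` is each network's edge count. Two identical networks give
#' `rho = 1`; disjoint edge sets give `rho = 0`. When both networks are
#' empty `rho = 1` by convention. The result lies in `[0, 1]` (for binary
#' matrices `d_H <= |a| + |b|` always, so clamping never alters the value).
#'
#' @param a,b Binary connectivity matrices of identical dimension and gene
#'   order.
#' @param method `"size"` (default) normalizes by `|a| + |b|`;
#'   `"strict"` normalizes by the number of candidate entries `I^2`
#'   (plain Hamming similarity). The size normalization is the one the
#'   replicate benchmark is calibrated on.
#' @return Stability value in `[0, 1]`.
#' @export
#' @examples
#' a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 3] <- 1L
#' b <- matrix(0L, 3, 3); b[1, 2] <- 1L
#' pairwise_stability(a, b) # 1 - 1/3
pairwise_stability <- function(a, b, method = c("size", "strict")) {
  method <- match.arg(method)
  a <- check_connectivity(a); b <- check_connectivity(b)
  check_same_genes(a, b)
  dh <- sum(a != b)
  denom <- switch(method, size = n_edges(a) + n_edges(b),
                  strict = length(a))
  if (denom == 0) return(1)
  clamp01(1 - dh / denom)
}

#' Overall stability of an ensemble of inferred networks
#'
#' Averages the pairwise stability over all `B(B-1)/2` unordered pairs of
#' an ensemble of networks inferred on replicate (or perturbed) datasets,
#' and reports the per-edge occurrence frequencies alongside.
#'
#' @param networks List of `B >= 2` binary connectivity matrices over the
#'   same genes.
#' @param method Normalization passed to [pairwise_stability()].
#' @return A list of class `stability_report` with elements `overall`
#'   (mean pairwise stability), `pairwise` (symmetric `B x B` matrix with
#'   unit diagonal), `edge_stability` (`I x I` occurrence-frequency
#'   matrix) and `n_networks`.
#' @export
overall_stability <- function(networks, method = c("size", "strict")) {
  method <- match.arg(method)
  if (!is.list(networks) || length(networks) < 2L)
    stop("`networks` must be a list of at least 2 connectivity matrices",
         call. = FALSE)
  B <- length(networks)
  pw <- diag(1, B)
  for (i in seq_len(B - 1L)) {
    for (j in seq.int(i + 1L, B)) {
      pw[i, j] <- pw[j, i] <-
        pairwise_stability(networks[[i]], networks[[j]], method = method)
    }
  }
  structure(list(overall = mean(pw[upper.tri(pw)]), pairwise = pw,
                 edge_stability = edge_stability(networks), n_networks = B),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability over %d networks: overall rho = %.3f\n",
              x$n_networks, x$overall))
  es <- x$edge_stability[x$edge_stability > 0]
  if (length(es))
    cat(sprintf("  %d edges ever observed; %d with frequency > 0.5\n",
                length(es), sum(es > 0.5)))
  invisible(x)
}

#' Per-edge stability (occurrence frequency)
#'
#' `e_ij` is the fraction of ensemble members in which edge `(i, j)`
#' occurs.
#'
#' @param networks Non-empty list of binary connectivity matrices over the
#'   same genes.
#' @return An `I x I` matrix of frequencies in `[0, 1]`.
#' @export
edge_stability <- function(networks) {
  if (!is.list(networks) || length(networks) < 1L)
    stop("`networks` must be a non-empty list", call. = FALSE)
  networks <- lapply(networks, check_connectivity)
  for (net in networks[-1L]) check_same_genes(networks[[1L]], net)
  Reduce(`+`, networks) / length(networks)
}

#' Consensus network of stable edges
#'
#' Keeps the edges whose occurrence frequency across the ensemble strictly
#' exceeds the threshold (edges at exactly the threshold are excluded,
#' matching the "stability greater than 0.5" rule).
#'
#' @param networks List of binary connectivity matrices, or a precomputed
#'   edge-stability matrix.
#' @param threshold Frequency threshold in `[0, 1]`; default 0.5.
#' @return A binary connectivity matrix.
#' @export
stable_network <- function(networks, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  es <- if (is.list(networks)) edge_stability(networks) else networks
  net <- (es > threshold) * 1L
  storage.mode(net) <- "integer"
  dimnames(net) <- dimnames(es)
  net
}

#' Accuracy of a predicted network against a ground truth
#'
#' Confusion counts over all `I^2` directed candidate entries (diagonal
#' included; direction matters), with precision = TP/(TP+FP), recall =
#' TP/(TP+FN) and F-measure their harmonic mean. Undefined ratios (empty
#' denominators) are reported as 0.
#'
#' @param predicted,truth Binary connectivity matrices of identical
#'   dimension and gene order.
#' @return A list of class `accuracy_report` with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f_measure`.
#' @export
network_accuracy <- function(predicted, truth) {
  predicted <- check_connectivity(predicted)
  truth <- check_connectivity(truth)
  check_same_genes(predicted, truth)
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, precision = precision,
                 recall = recall, f_measure = f),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf(
    "TP %d  FP %d  FN %d  TN %d | precision %.3f recall %.3f F %.3f\n",
    x$tp, x$fp, x$fn, x$tn, x$precision, x$recall, x$f_measure))
  invisible(x)
}
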