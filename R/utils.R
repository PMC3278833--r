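# Internal helpers shared across modules.

# Run code under a temporary RNG seed; NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a reproducible child seed from a parent seed
#'
#' Folds one or more integer keys into a parent seed with a multiplicative
#' congruential step, so that every cell and replicate of an experiment gets
#' its own reproducible seed below `2^31`. Used by
#' [run_synthetic_benchmark()] and [run_perturbation_study()] to make any
#' single replicate re-runnable in isolation.
#'
#' @param seed Integer parent seed.
#' @param ... Integer keys (e.g. network size, time points, replicate id).
#' @return A single integer seed in `[0, 2147483562]`.
#' @export
#' @examples
#' derive_seed(42, 10, 30, 1)
derive_seed <- function(seed, ...) {
  keys <- c(...)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- as.double(seed) %% 2147483563
  for (k in keys) s <- (s * 69069 + as.double(k)) %% 2147483563
  as.integer(s)
}

default_gene_labels <- function(n) paste0("G", seq_len(n))

# Validate (and label) a binary connectivity matrix.
check_connectivity <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(sprintf("`%s` must be a square matrix", arg), call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0/1 entries", arg), call. = FALSE)
  if (is.null(rownames(x))) {
    lab <- default_gene_labels(nrow(x))
    dimnames(x) <- list(lab, lab)
  }
  storage.mode(x) <- "integer"
  x
}

check_same_genes <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("networks must have identical dimensions", call. = FALSE)
  if (!is.null(rownames(a)) && !is.null(rownames(b)) &&
      !identical(rownames(a), rownames(b)))
    stop("networks must share the same gene labels in the same order",
         call. = FALSE)
  invisible(TRUE)
}

n_edges <- function(net) sum(net != 0)

clamp01 <- function(x) pmin(1, pmax(0, x))
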