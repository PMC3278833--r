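# Independent oracles and small fixture builders used across the suite.

# Elastic-net objective on the package's parameterization.
enet_objective <- function(Z, y, b, lambda, alpha) {
  n <- nrow(Z)
  sum((y - Z %*% b)^2) / (2 * n) +
    lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
}

# Largest violation of the elastic-net KKT (subgradient) conditions.
kkt_violation <- function(Z, y, b, lambda, alpha) {
  n <- nrow(Z)
  g <- drop(crossprod(Z, y - Z %*% b)) / n - lambda * (1 - alpha) * b
  v <- 0
  nz <- b != 0
  if (any(nz))
    v <- max(v, max(abs(g[nz] - lambda * alpha * sign(b[nz]))))
  if (any(!nz))
    v <- max(v, max(0, max(abs(g[!nz])) - lambda * alpha))
  v
}

# Hand-executed Benjamini-Hochberg step-up: reject the k* smallest
# p-values where k* is the largest k with P_(k) <= (k/n) q.
bh_stepup <- function(p, q) {
  n <- length(p)
  o <- order(p)
  ks <- which(p[o] <= seq_len(n) / n * q)
  reject <- rep(0L, n)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- 1L
  reject
}

# Random binary network over I genes with ne edges (no self-edges).
random_network <- function(I, ne, seed) {
  withr::with_seed(seed, {
    net <- matrix(0L, I, I)
    off <- which(row(net) != col(net))
    net[sample(off, ne)] <- 1L
    lab <- paste0("G", seq_len(I))
    dimnames(net) <- list(lab, lab)
    net
  })
}

# A persistently excited sparse VAR truth: scale-free cross-regulation
# plus uniform self-decay, so long simulated series identify the support.
stationary_truth <- function(I = 10, self = 0.5, seed = 2) {
  net <- generate_scale_free(I, seed = seed)
  beta <- sample_coefficients(net, seed = seed + 1L)
  diag(beta) <- self
  beta
}
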