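#' Detect network edges by coefficient magnitude
#'
#' Declares a directed regulatory edge `i -> j` whenever
#' `|beta_hat[i, j]| > epsilon`. All `I^2` entries, including the diagonal
#' (self-regulation), are candidate edges.
#'
#' @param model An `mvar_model`, or a coefficient matrix directly.
#' @param epsilon Magnitude cutoff (>= 0). Default `1e-4`, the cutoff used
#'   throughout the synthetic study.
#' @return A binary connectivity matrix.
#' @export
detect_edges <- function(model, epsilon = 1e-4) {
  beta <- if (inherits(model, "mvar_model")) model$beta_hat else model
  if (!is.matrix(beta)) stop("`model` must be an mvar_model or a matrix",
                             call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop("`epsilon` must be a single non-negative number", call. = FALSE)
  net <- (abs(beta) > epsilon) * 1L
  storage.mode(net) <- "integer"
  dimnames(net) <- dimnames(beta)
  net
}

# t-based p-value matrix for penalized coefficients.  For target j with
# coefficients b, the sandwich (Z'Z + lam W^-)^{-1} Z'Z (Z'Z + lam W^-)^{-1}
# is formed with W^- the pseudo-inverse of diag(|b|) (zero coefficients
# contribute zero); the statistic b_k / sqrt(sigma2 * w_k) is referred to a
# t distribution with d = nonzero-coefficient-count degrees of freedom.
# Zero coefficients receive p = 1 by convention.
pvalue_matrix <- function(beta_hat, Z, lambda_eff, dof, sigma2) {
  p <- ncol(Z)
  G <- crossprod(Z)
  pv <- matrix(1, p, ncol(beta_hat))
  wd <- matrix(NA_real_, p, ncol(beta_hat))
  for (j in seq_len(ncol(beta_hat))) {
    b <- beta_hat[, j]
    d <- dof[j]
    nz <- b != 0
    if (!any(nz)) next
    if (d <= 0)
      stop(sprintf(
        "target %d has a nonempty support but %g degrees of freedom", j, d),
        call. = FALSE)
    winv <- ifelse(nz, 1 / abs(b), 0)
    A <- G + diag(lambda_eff[j] * winv, p)
    Ainv <- tryCatch(solve(A), error = function(e) {
      warning("singular penalized information matrix; using pseudo-inverse",
              call. = FALSE)
      MASS::ginv(A)
    })
    w <- diag(Ainv %*% G %*% Ainv)
    wd[, j] <- w
    tstat <- b / sqrt(pmax(sigma2[j] * w, .Machine$double.xmin))
    pj <- 2 * pt(-abs(tstat), df = d)
    pj[!nz] <- 1
    pv[, j] <- pj
  }
  dimnames(pv) <- dimnames(beta_hat)
  list(pvalues = pv, w_diag = wd)
}

#' Approximate significance of penalized MVAR coefficients
#'
#' Computes a two-sided t-based p-value for every coefficient of a fitted
#' penalized MVAR model, then selects the significant edges by
#' Benjamini–Hochberg FDR control over all `I^2` coefficients of the model.
#' The standard error of coefficient `k` of target `j` uses the
#' ridge-approximation sandwich
#' `w_k = [(Z'Z + lam W^-)^{-1} Z'Z (Z'Z + lam W^-)^{-1}]_kk`, with `W` the
#' diagonal matrix of `|beta_k|`, `W^-` its generalized (pseudo) inverse,
#' and `lam` the tuned penalty on the effective scale (`n * lambda`). The
#' degrees of freedom are the number of nonzero coefficients of the target
#' (an unbiased estimate for the lasso, adopted for the elastic-net as
#' well), and `sigma^2` is the residual variance estimate of the target.
#' Exactly-zero coefficients receive p = 1.
#'
#' @param model A fitted `mvar_model` (lasso, elastic-net or ridge).
#' @param design The [build_design()] result the model was fitted on.
#' @param q FDR level in (0, 1); default 0.05.
#' @param dof_method Reference degrees of freedom for the t distribution:
#'   `"residual"` (default) uses the classical `n - d` with `d` the
#'   nonzero-coefficient count of the target; `"nonzero"` uses `d` itself
#'   (the lasso degrees-of-freedom convention). The nonzero count always
#'   enters the residual-variance denominator.
#' @return A list of class `grn_significance` with elements `pvalues`
#'   (`I x I` matrix), `significant` (binary BH rejection mask), `q`,
#'   `dof_used` and `w_diag`.
#' @export
coefficient_pvalues <- function(model, design, q = 0.05,
                                dof_method = c("residual", "nonzero")) {
  stopifnot(inherits(model, "mvar_model"), inherits(design, "mvar_design"))
  dof_method <- match.arg(dof_method)
  if (!identical(ncol(model$beta_hat), ncol(design$Z)))
    stop("model and design dimensions disagree", call. = FALSE)
  dof <- tdof_of(model, dof_method)
  res <- pvalue_matrix(model$beta_hat, design$Z,
                       lambda_eff = model$n_obs * model$lambda,
                       dof = dof, sigma2 = model$resid_sigma2)
  mask <- fdr_select(res$pvalues, q)
  structure(list(pvalues = res$pvalues, significant = mask, q = q,
                 dof_used = dof, w_diag = res$w_diag),
            class = "grn_significance")
}

tdof_of <- function(model, dof_method) {
  switch(dof_method,
         nonzero = model$dof,
         residual = pmax(model$n_obs - model$dof, 1))
}

#' Significant-edge network of a sparse MVAR model
#'
#' Declares an edge for every coefficient on the fitted support whose
#' two-sided t-based p-value (see [coefficient_pvalues()]) falls below
#' `level`, without multiplicity correction: the per-coefficient
#' significance rule used to read edges off lasso and elastic-net fits in
#' the replicate benchmark. Use [coefficient_pvalues()] with its FDR mask
#' when family-wise false-discovery control is wanted instead.
#'
#' @param model A fitted `mvar_model`.
#' @param design The [build_design()] result the model was fitted on.
#' @param level Per-coefficient significance level; default 0.05.
#' @param dof_method See [coefficient_pvalues()].
#' @param epsilon Magnitude cutoff applied alongside the test.
#' @return A binary connectivity matrix.
#' @export
significant_edges <- function(model, design, level = 0.05,
                              dof_method = c("residual", "nonzero"),
                              epsilon = 1e-4) {
  stopifnot(inherits(model, "mvar_model"), inherits(design, "mvar_design"))
  dof_method <- match.arg(dof_method)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("`level` must be in (0, 1)", call. = FALSE)
  res <- pvalue_matrix(model$beta_hat, design$Z,
                       lambda_eff = model$n_obs * model$lambda,
                       dof = tdof_of(model, dof_method),
                       sigma2 = model$resid_sigma2)
  net <- ((res$pvalues < level) & (abs(model$beta_hat) > epsilon)) * 1L
  storage.mode(net) <- "integer"
  dimnames(net) <- dimnames(model$beta_hat)
  net
}

#' Benjamini–Hochberg FDR edge selection
#'
#' Step-up FDR control over all supplied p-values (for a fitted model the
#' family is the full set of `I^2` coefficient hypotheses): with sorted
#' p-values `P_(1) <= ... <= P_(n)`, all hypotheses up to the largest `k`
#' with `P_(k) <= (k/n) q` are rejected.
#'
#' @param pvalues Numeric matrix (or vector) of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return A binary rejection mask of the same shape.
#' @export
#' @examples
#' fdr_select(c(0.001, 0.008, 0.039, 0.041, 0.6), q = 0.05)
fdr_select <- function(pvalues, q) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("`q` must be in (0, 1)", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  mask <- (p.adjust(as.vector(pvalues), method = "BH") <= q) * 1L
  if (is.matrix(pvalues)) {
    mask <- matrix(mask, nrow(pvalues), ncol(pvalues),
                   dimnames = dimnames(pvalues))
    storage.mode(mask) <- "integer"
  }
  mask
}
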