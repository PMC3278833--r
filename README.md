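# grnstab

Inference of gene regulatory networks (GRNs) from short gene-expression
time series with penalized first-order vector autoregression, and
quantification of how *stable* — reproducible across replicate or
perturbed data — the inferred network structure is.

GRNs built from temporal expression data are notoriously fragile: with
tens of time points and tens-to-hundreds of genes the estimation problem
is ill-posed, and rerunning the same pipeline on replicate data can
return a visibly different network. `grnstab` is for computational
biologists and methods researchers who want to (a) build lag-1 networks
with ridge, lasso or elastic-net MVAR models, (b) attach stability
scores to the resulting structure, and (c) study accuracy/stability
trade-offs by simulation on scale-free ground truths.

## The model and the criteria

Expression dynamics follow a first-order multivariate vector
autoregression: with row vector $y^t$ of all genes' expressions at time
$t$,

$$y^t = y^{t-1}\beta + \varepsilon^t,$$

where $\beta_{ij} \neq 0$ means gene $i$ regulates gene $j$ at lag one.
Each column of $\beta$ is estimated by penalized least squares,

$$\hat\beta_j = \arg\min_b \tfrac{1}{2n}\lVert Y_j - Zb\rVert^2 +
\lambda\big(\alpha\lVert b\rVert_1 + \tfrac{1-\alpha}{2}\lVert b\rVert^2\big),$$

with $\alpha = 0$ (ridge), $1$ (lasso) or $\alpha \in (0,1)$
(elastic-net), and $\lambda$ (and $\alpha$) tuned by leave-one-out
cross-validation. Edges are read off either by magnitude cutoff or by an
approximate t-test on the penalized coefficients, with
Benjamini–Hochberg FDR control available for real-data workflows.

Stability of a collection of networks $s^1,\dots,s^B$ inferred from
replicate data is scored by the Hamming-based pairwise similarity
$\rho(s^a,s^b) = 1 - d_H(s^a,s^b)/(|s^a|+|s^b|) \in [0,1]$, its average
$\bar\rho$ over all pairs (overall stability), and the per-edge
occurrence frequency $e_{ij}$ (edge stability); edges with $e_{ij} >
0.5$ form the consensus "stable network".

A synthetic-data module generates directed scale-free topologies by
preferential attachment ($p_i \propto d_i^{\gamma} + b$, with in-degree
$d_i$ and attachment power $\gamma = 1.2$ by default), draws true
coefficients with magnitudes uniform on $[0.8, 1]$ and balanced signs,
simulates series from uniform $[10, 15]$ initial expressions with unit
innovation covariance, and injects Gaussian perturbation noise of
standard deviation $\sigma + \delta$ calibrated to a target
signal-to-noise ratio.

## Worked example

```r
library(grnstab)

net  <- generate_scale_free(10, seed = 1)        # 9-edge ground truth
beta <- sample_coefficients(net, seed = 2)       # |beta| in [0.8, 1]
x    <- simulate_timeseries(beta, 50, seed = 3)  # 10 genes x 50 points

fit <- loocv_tune(x, "lasso")
fit
#> MVAR(1) model: 10 genes, penalty = lasso, 49 design rows
#>   lambda: [0.00215, 1.257], alpha: [1, 1]
#>   nonzero coefficients: 37 of 100

grn <- significant_edges(fit, build_design(x), level = 0.05)
network_accuracy(grn, net)
#> TP 9  FP 5  FN 0  TN 86 | precision 0.643 recall 1.000 F 0.783
```

The tuned lasso keeps 37 of 100 candidate coefficients; the
per-coefficient significance filter trims these to the 9 true edges plus
5 false positives (recall 1.00, F 0.78). Stability across replicate
series of the same truth:

```r
nets <- lapply(1:20, function(b) {
  xb <- simulate_timeseries(beta, 50, seed = 100 + b)
  f  <- loocv_tune(xb, "lasso")
  significant_edges(f, build_design(xb), level = 0.05)
})
overall_stability(nets)
#> Stability over 20 networks: overall rho = 0.740
#>   56 edges ever observed; 9 with frequency > 0.5
```

The 9 edges occurring in more than half of the replicates — the stable
network (`stable_network(nets)`) — are exactly the true ones here, while
the false positives churn: that gap between $\bar\rho = 0.74$ and 1 is
what the stability criteria are designed to expose.

Full simulation studies run through `experiment_config()` /
`run_synthetic_benchmark()` (accuracy and stability over a grid of
network sizes, series lengths and methods) and
`run_perturbation_study()` (stability of significant edges under
increasing noise on a fixed dataset). A thin command-line interface over
these functions ships in `inst/cli/grnstab.R`.

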