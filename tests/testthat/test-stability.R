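net_from_edges <- function(I, edges) {
  net <- matrix(0L, I, I, dimnames = list(paste0("G", 1:I), paste0("G", 1:I)))
  for (e in edges) net[e[1], e[2]] <- 1L
  net
}

test_that("pairwise stability follows the Hamming-based definition", {
  a <- net_from_edges(3, list(c(1, 2), c(2, 3)))
  b <- net_from_edges(3, list(c(1, 2)))
  expect_equal(pairwise_stability(a, a), 1)
  expect_equal(pairwise_stability(a, b), 1 - 1 / 3, tolerance = 1e-12)
  # disjoint edge sets of sizes 3 and 2: maximal disagreement
  d1 <- net_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  d2 <- net_from_edges(4, list(c(2, 1), c(3, 1)))
  expect_equal(pairwise_stability(d1, d2), 0)
  # both empty: 1 by convention
  expect_equal(pairwise_stability(net_from_edges(3, list()),
                                  net_from_edges(3, list())), 1)
  # strict normalization uses the candidate count
  expect_equal(pairwise_stability(a, b, method = "strict"), 1 - 1 / 9)
  expect_error(pairwise_stability(a, net_from_edges(4, list())),
               "identical dimensions")
})

test_that("pairwise stability is symmetric, bounded and maximal only for
           identical networks", {
  for (r in 1:500) {
    a <- random_network(6, sample(0:8, 1), seed = 2 * r)
    b <- random_network(6, sample(0:8, 1), seed = 2 * r + 1)
    rho <- pairwise_stability(a, b)
    expect_identical(rho, pairwise_stability(b, a))
    expect_true(rho >= 0 && rho <= 1)
    # the Hamming distance never exceeds |a| + |b| (clamping is a no-op)
    expect_lte(sum(a != b), sum(a) + sum(b))
    if (rho == 1 && sum(a) + sum(b) > 0) expect_identical(a, b)
  }
})

test_that("overall stability averages the pairwise upper triangle", {
  a <- net_from_edges(3, list(c(1, 2)))
  c3 <- net_from_edges(3, list(c(3, 1)))
  rep3 <- overall_stability(list(a, a, c3))
  expect_equal(rep3$overall, mean(c(1, 0, 0)))
  expect_equal(rep3$pairwise, t(rep3$pairwise))
  expect_true(all(diag(rep3$pairwise) == 1))
  expect_equal(rep3$overall,
               mean(rep3$pairwise[upper.tri(rep3$pairwise)]))
  # identical members give perfect stability
  expect_equal(overall_stability(list(a, a, a, a))$overall, 1)
  # order invariance
  nets <- lapply(1:5, function(r) random_network(5, 4, seed = 40 + r))
  perm <- nets[c(3, 5, 1, 4, 2)]
  expect_equal(overall_stability(nets)$overall,
               overall_stability(perm)$overall)
  expect_error(overall_stability(list(a)), "at least 2")
})

test_that("edge stability is the occurrence frequency", {
  e1 <- net_from_edges(3, list(c(1, 2)))
  e0 <- net_from_edges(3, list())
  es <- edge_stability(list(e1, e0, e1, e1))
  expect_equal(es[1, 2], 0.75)
  expect_true(all(es[-4] >= 0))
  # constant ensembles return the member exactly
  expect_equal(edge_stability(list(e1, e1)), e1, ignore_attr = TRUE)
  # frequency equals the elementwise mean
  nets <- lapply(1:6, function(r) random_network(4, 3, seed = 60 + r))
  manual <- Reduce(`+`, nets) / 6
  expect_equal(edge_stability(nets), manual, ignore_attr = TRUE)
})

test_that("the consensus network keeps edges strictly above threshold", {
  e1 <- net_from_edges(3, list(c(1, 2), c(2, 3)))
  e2 <- net_from_edges(3, list(c(1, 2)))
  ens <- list(e1, e2)
  # edge (2,3) has frequency exactly 0.5: excluded at threshold 0.5
  cons <- stable_network(ens, 0.5)
  expect_equal(cons[1, 2], 1L)
  expect_equal(cons[2, 3], 0L)
  # threshold 0 keeps everything ever observed
  expect_equal(stable_network(ens, 0), (edge_stability(ens) > 0) * 1L,
               ignore_attr = TRUE)
  # threshold 1 keeps nothing unless present everywhere
  expect_equal(sum(stable_network(ens, 1)), 0L)
  expect_equal(sum(stable_network(list(e1, e1), 1)), 0L)
  expect_error(stable_network(ens, 2), "\\[0, 1\\]")
})

test_that("accuracy scores directed candidate entries with the diagonal", {
  truth <- random_network(10, 9, seed = 70)
  all_edges <- matrix(1L, 10, 10,
                      dimnames = dimnames(truth))
  a <- network_accuracy(all_edges, truth)
  expect_equal(a$recall, 1)
  expect_equal(a$precision, 0.09)
  expect_equal(a$tp + a$fp + a$fn + a$tn, 100L)
  perfect <- network_accuracy(truth, truth)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_measure),
               c(1, 1, 1))
  # direction matters
  fwd <- net_from_edges(3, list(c(1, 2)))
  rev <- net_from_edges(3, list(c(2, 1)))
  arev <- network_accuracy(rev, fwd)
  expect_equal(arev$tp, 0L)
  expect_equal(arev$precision + arev$recall, 0)
  # count identities on random pairs
  for (r in 1:50) {
    p <- random_network(7, sample(0:10, 1), seed = 80 + 2 * r)
    t2 <- random_network(7, sample(0:10, 1), seed = 81 + 2 * r)
    acc <- network_accuracy(p, t2)
    expect_equal(acc$tp + acc$fn, sum(t2))
    expect_equal(acc$tp + acc$fp, sum(p))
  }
})
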