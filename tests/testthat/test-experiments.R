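test_that("false-rejection experiments are reproducible and monotone in alpha", {
  tree <- random_chronogram(6, 0.5, seed = 71)
  r1 <- false_rejection_experiment(tree, jc_model(), length = 300,
                                   n_reps = 25, seed = 72)
  r2 <- false_rejection_experiment(tree, jc_model(), length = 300,
                                   n_reps = 25, seed = 72)
  expect_identical(r1$results, r2$results)
  expect_equal(r1$summary$n_ok, 25)
  expect_gte(r1$summary$ci_high, r1$summary$rejection_rate)
  # stricter alpha can only reject less often on the same replicates
  expect_lte(mean(r1$results$p_value < 0.01),
             mean(r1$results$p_value < 0.05))
  expect_error(false_rejection_experiment(ape::rtree(6)), "ultrametric")
})

test_that("node-age error is zero for the truth and scale-invariant", {
  tr <- random_chronogram(9, 0.5, seed = 73)
  expect_equal(dating_error(tr, tr)$total, 0)
  expect_equal(dating_error(tr, rescale_height(tr, 3))$total, 0,
               tolerance = 1e-9)
  expect_equal(dating_error(tr, tr)$n_nodes, 8L)
  other <- simulate_yule(9, 1, seed = 74)
  expect_error(dating_error(tr, other), "same clades")
})

test_that("strict-clock dating recovers relative node ages from clock data", {
  chr <- random_chronogram(8, 0.5, seed = 75)
  aln <- simulate_alignment(chr, jc_model(), 20000, seed = 76)
  fit <- strict_clock_ml_dating(aln, chr)
  expect_true(is_ultrametric(fit$tree, tol = 1e-6))
  expect_equal(tree_height(fit$tree), 1, tolerance = 1e-6)
  expect_lt(tree_stats(fit$tree)$rtt_variance, 1e-12)
  err <- dating_error(chr, fit$tree)
  expect_lt(err$total / (err$n_nodes * tree_height(chr)), 0.03)

  # three identical genes carry the same information as one triple-length
  # gene: the fitted chronograms agree
  fit3 <- strict_clock_ml_dating(list(aln, aln, aln), chr)
  expect_equal(node_heights(fit3$tree), node_heights(fit$tree),
               tolerance = 1e-3)
  expect_equal(fit3$rates, rep(fit$rates[1], 3), tolerance = 1e-3)
})

test_that("gene-specific rates rescale cleanly in joint dating", {
  chr <- random_chronogram(7, 0.5, seed = 77)
  fast <- chr; fast$edge.length <- fast$edge.length * 3
  a1 <- simulate_alignment(chr, jc_model(), 8000, seed = 78)
  a2 <- simulate_alignment(fast, jc_model(), 8000, seed = 79)
  fit <- strict_clock_ml_dating(list(a1, a2), chr)
  expect_equal(fit$rates[2] / fit$rates[1], 3, tolerance = 0.15)
  expect_lt(dating_error(chr, fit$tree)$total, 0.1)
})

test_that("a small shopped-vs-random run is deterministic and well-formed", {
  rep1 <- shopping_vs_random_experiment(n_trials = 2, n_taxa = 8,
                                        n_genes = 30, length = 300,
                                        seed = 80)
  rep2 <- shopping_vs_random_experiment(n_trials = 2, n_taxa = 8,
                                        n_genes = 30, length = 300,
                                        seed = 80)
  expect_identical(rep1$results, rep2$results)
  expect_equal(nrow(rep1$results), 2L)
  expect_true(all(rep1$results$ok))
  expect_true(all(rep1$results$error_shopped >= 0))
  expect_true(all(rep1$results$error_random >= 0))
})

test_that("the heterogeneity landscape separates clock from relaxed-clock pools", {
  chr <- random_chronogram(10, 0.5, seed = 81)
  set.seed(82)
  pool <- function(dec, n) lapply(seq_len(n), function(i)
    apply_rates(chr, dec))
  pools <- list(
    clock = pool(rate_decoration("strict"), 30),
    ucln05 = pool(rate_decoration("ucln", mean_log = -0.5,
                                  stdev_log = 0.5), 30),
    ucln10 = pool(rate_decoration("ucln", mean_log = -0.5,
                                  stdev_log = 1.0), 30))
  rep <- heterogeneity_landscape(pools)
  med <- rep$summary
  expect_lt(med$clock["median_rtt_variance"], 1e-15)
  expect_gt(med$ucln10["median_rtt_variance"],
            med$ucln05["median_rtt_variance"])
  dev_sums <- tapply(rep$deviations$deviation,
                     paste(rep$deviations$condition, rep$deviations$gene),
                     sum)
  expect_true(all(abs(dev_sums) < 1e-9))
})
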