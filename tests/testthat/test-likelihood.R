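test_that("log-likelihood matches closed forms for two taxa", {
  tr <- read_newick("(a:0.05,b:0.05);")
  aln <- as_phyDat_states(matrix(c(1L, 1L), 2, 1,
                                 dimnames = list(c("a", "b"), NULL)), "DNA")
  expect_equal(log_likelihood(aln, tr),
               log(0.25 * (0.25 + 0.75 * exp(-4 * 0.1 / 3))),
               tolerance = 1e-8)

  # differing states, and the amino-acid analogue
  aln2 <- as_phyDat_states(matrix(c(1L, 3L), 2, 1,
                                  dimnames = list(c("a", "b"), NULL)), "DNA")
  p <- transition_prob(jc_model(), 0.1)
  expect_equal(log_likelihood(aln2, tr), log(0.25 * p$diff),
               tolerance = 1e-8)

  aa <- as_phyDat_states(matrix(c(4L, 4L), 2, 1,
                                dimnames = list(c("a", "b"), NULL)), "AA")
  pa <- transition_prob(poisson_model(), 0.1)
  expect_equal(log_likelihood(aa, tr), log(pa$same / 20), tolerance = 1e-8)

  # zero branch lengths, identical sequences of length L
  tr0 <- read_newick("(a:0,b:0);")
  L <- 7
  aln0 <- as_phyDat_states(matrix(2L, 2, L,
                                  dimnames = list(c("a", "b"), NULL)), "DNA")
  expect_equal(log_likelihood(aln0, tr0), L * log(0.25), tolerance = 1e-10)
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  set.seed(13)
  for (i in 1:6) {
    n <- sample(4:5, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.8)
    seqs <- matrix(sample.int(4, n * 3, replace = TRUE), n, 3,
                   dimnames = list(tr$tip.label, NULL))
    expect_equal(log_likelihood(as_phyDat_states(seqs, "DNA"), tr),
                 oracle_lnl(tr, seqs, 4), tolerance = 1e-8)
  }
  # amino-acid engine against the same enumeration
  tr <- ape::rtree(4)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  seqs <- matrix(sample.int(20, 4 * 2, replace = TRUE), 4, 2,
                 dimnames = list(tr$tip.label, NULL))
  expect_equal(log_likelihood(as_phyDat_states(seqs, "AA"), tr),
               oracle_lnl(tr, seqs, 20), tolerance = 1e-8)
})

test_that("likelihood is invariant to root placement and agrees with an independent engine", {
  set.seed(17)
  tr <- ape::rtree(6)
  aln <- simulate_alignment(tr, jc_model(), 300)
  l0 <- log_likelihood(aln, tr)
  for (og in sample(tr$tip.label, 3))
    expect_equal(log_likelihood(aln, root_by_outgroup(tr, og)), l0,
                 tolerance = 1e-8)
  expect_equal(l0, as.numeric(phangorn::pml(tr, aln)$logLik),
               tolerance = 1e-6)

  # gaps/ambiguities as missing data, same convention as the oracle engine
  m <- as.character(aln)
  m[1, 1:20] <- "-"
  m[2, 5:10] <- "n"
  alng <- phangorn::phyDat(m, type = "DNA")
  expect_equal(log_likelihood(alng, tr),
               as.numeric(phangorn::pml(tr, alng)$logLik), tolerance = 1e-6)

  expect_error(log_likelihood(aln, read_newick("(t1:1,(t2:1,zz:1):1);")),
               "taxon mismatch")
})

test_that("free branch-length optimization reaches the independent optimizer's maximum", {
  set.seed(23)
  tr <- ape::rtree(6)
  aln <- simulate_alignment(tr, jc_model(), 400)
  mine <- optimize_free(aln, tr)
  expect_gte(mine$logLik, log_likelihood(aln, tr) - 1e-9)
  ref <- phangorn::optim.pml(phangorn::pml(ape::unroot(tr), aln),
                             optEdge = TRUE,
                             control = phangorn::pml.control(trace = 0))
  expect_equal(mine$logLik, as.numeric(ref$logLik), tolerance = 1e-3)

  # constant alignment drives all branch lengths to zero
  const <- as_phyDat_states(matrix(1L, 6, 10,
                                   dimnames = list(tr$tip.label, NULL)),
                            "DNA")
  expect_lt(max(optimize_free(const, tr)$tree$edge.length), 1e-6)
})

test_that("clock optimization yields an ultrametric tree dominated by the free fit", {
  set.seed(29)
  for (i in 1:3) {
    chr <- random_chronogram(7, 0.5)
    aln <- simulate_alignment(chr, jc_model(), 500)
    free <- optimize_free(aln, chr)
    clk <- optimize_clock(aln, chr)
    expect_true(is_ultrametric(clk$tree, tol = 1e-6))
    expect_lte(clk$logLik, free$logLik + 1e-6)
    expect_lt(tree_stats(clk$tree)$rtt_variance, 1e-12)
  }
})

test_that("the clock LRT uses n-2 degrees of freedom and a chi-square tail", {
  chr <- random_chronogram(11, 0.5, seed = 37)
  aln <- simulate_alignment(chr, jc_model(), 400, seed = 38)
  r <- clock_lrt(aln, chr)
  expect_equal(r$df, 9L)
  expect_gte(r$statistic, 0)
  expect_equal(r$p_value,
               pchisq(r$statistic, df = 9, lower.tail = FALSE))

  chr3 <- read_newick("((a:0.2,b:0.2):0.1,c:0.3);")
  aln3 <- simulate_alignment(chr3, jc_model(), 300, seed = 39)
  expect_equal(clock_lrt(aln3, chr3)$df, 1L)

  # strongly rate-heterogeneous data must reject the clock
  ucln <- apply_rates(random_chronogram(11, 0.5, seed = 40),
                      rate_decoration("ucln", mean_log = -0.5,
                                      stdev_log = 1.0),
                      seed = 41)
  alnu <- simulate_alignment(ucln, jc_model(), 1500, seed = 42)
  expect_true(clock_lrt(alnu, chr)$rejected)
})
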