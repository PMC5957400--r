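test_that("Newick parsing validates input and round-trips random trees", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L) # root with two children

  expect_error(read_newick("();"), "parse error")
  expect_error(read_newick("((A:1,B:1):1,A:2);"), "duplicate tip labels")
  expect_error(read_newick("((A:1,B:1:1,C:2);"), "parse error")

  set.seed(101)
  for (i in 1:50) {
    t0 <- simulate_yule(sample(4:15, 1), 1)
    t1 <- read_newick(write_newick(t0))
    expect_equal(sort(t1$tip.label), sort(t0$tip.label))
    expect_true(ape::all.equal.phylo(t0, t1, use.edge.length = TRUE,
                                     tolerance = 1e-10))
  }
})

test_that("outgroup rooting places the root on the separating edge and conserves length", {
  tr <- read_newick("(A:1,B:1,(C:1,D:1):1);")
  rooted <- root_by_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  kid_tips <- lapply(kids, function(v)
    if (v <= ape::Ntip(rooted)) rooted$tip.label[v]
    else ape::extract.clade(rooted, v)$tip.label)
  expect_true(any(vapply(kid_tips, function(x) identical(x, "D"), TRUE)))
  expect_equal(sum(rooted$edge.length), sum(tr$edge.length))

  expect_error(root_by_outgroup(read_newick("((A:1,B:1):1,(C:1,D:1):1);"),
                                c("A", "C")),
               "not separable")
  expect_error(root_by_outgroup(tr, "Z"), "not in tree")

  # rerooting is a no-op on the unrooted bipartition set
  set.seed(77)
  for (i in 1:10) {
    t0 <- ape::rtree(8)
    og <- sample(t0$tip.label, 1)
    r <- root_by_outgroup(t0, og)
    expect_equal(sum(r$edge.length), sum(t0$edge.length), tolerance = 1e-12)
    expect_equal(as.character(extract_bipartitions(r)),
                 as.character(extract_bipartitions(t0)))
  }
})

test_that("pruning preserves surviving root-to-tip paths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  pr <- prune_taxa(tr, "C", min_tips = 2)
  st <- tree_stats(pr)
  expect_equal(unname(st$root_to_tip[c("A", "B")]), c(2, 2))
  expect_equal(st$tree_length, 3) # A + B branches plus retained stem

  expect_error(prune_taxa(tr, "X"), "not in tree")
  expect_error(prune_taxa(read_newick("((A:1,B:1):1,(C:1,D:1):1);"),
                          c("C", "D")),
               "would leave")

  set.seed(42)
  for (i in 1:10) {
    t0 <- ape::rtree(10)
    drop <- sample(t0$tip.label, 3)
    before <- tree_stats(t0)$root_to_tip
    after <- tree_stats(prune_taxa(t0, drop))$root_to_tip
    expect_equal(after, before[names(after)], tolerance = 1e-12)
  }
})

test_that("tree statistics match hand-computed values and the clock invariant", {
  st <- tree_stats(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(unname(st$root_to_tip), c(2, 2, 2))
  expect_equal(st$rtt_variance, 0)
  expect_equal(st$tree_length, 5)

  st2 <- tree_stats(read_newick("((A:1,B:2):1,C:2);"))
  expect_equal(st2$rtt_variance, 1 / 3) # sample variance of {2, 3, 2}
  expect_equal(sum(st2$rtt_deviations), 0, tolerance = 1e-12)

  # strict-clock trees are ultrametric with zero root-to-tip variance
  set.seed(7)
  for (i in 1:20) {
    tr <- simulate_yule(sample(5:12, 1), 1)
    expect_true(is_ultrametric(tr))
    expect_lt(tree_stats(tr)$rtt_variance, 1e-18)
    expect_gte(tree_stats(tr)$tree_length,
               max(tree_stats(tr)$root_to_tip))
  }

  # and perturbing any branch breaks ultrametricity and the zero variance
  tr <- simulate_yule(8, 1, seed = 3)
  tr$edge.length[5] <- tr$edge.length[5] + 0.1
  expect_false(is_ultrametric(tr))
  expect_gt(tree_stats(tr)$rtt_variance, 0)
})
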