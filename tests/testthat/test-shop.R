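test_that("ranking follows the winnowing order with stable ties and thresholds", {
  recs <- data.frame(gene = c("g1", "g2", "g3"),
                     concordance = c(1.0, 0.8, 1.0),
                     rtt_variance = c(0.01, 0.001, 0.002),
                     tree_length = c(2.0, 5.0, 1.0))
  expect_equal(rank_genes(recs)$gene, c("g3", "g1", "g2"))

  # all-equal records keep their input order (stability)
  same <- data.frame(gene = c("b", "a", "c"), concordance = 1,
                     rtt_variance = 0.1, tree_length = 2)
  expect_equal(rank_genes(same)$gene, c("b", "a", "c"))

  pol <- ranking_policy(thresholds = list(concordance = 0.9))
  expect_equal(rank_genes(recs, pol)$gene, c("g3", "g1"))

  pol_all <- ranking_policy(thresholds = list(concordance = 2))
  expect_warning(out <- rank_genes(recs, pol_all), "excluded")
  expect_equal(nrow(out), 0L)

  # ranking is invariant to input row order for distinct records
  shuffled <- recs[c(2, 3, 1), ]
  expect_equal(rank_genes(shuffled)$gene, c("g3", "g1", "g2"))

  # alternative criterion order puts tree length first
  pol2 <- ranking_policy(order = c("tree_length", "concordance",
                                   "rtt_variance"))
  expect_equal(rank_genes(recs, pol2)$gene, c("g2", "g1", "g3"))
  expect_error(ranking_policy(order = c("tree_length", "tree_length",
                                        "rtt_variance")),
               "permutation")
})

test_that("gene statistics agree with independently invoked per-gene operations", {
  sp <- fixture_species_tree_for_tests(10, 0.5, seed = 61)
  genes <- list()
  set.seed(62)
  decs <- list(rate_decoration("strict"),
               rate_decoration("noisy_clock", rate = 1, noise_sd = 0.5),
               rate_decoration("ucln", mean_log = -0.5, stdev_log = 1))
  for (i in seq_along(decs)) genes[[paste0("g", i)]] <- apply_rates(sp, decs[[i]])

  tab <- compute_gene_stats(genes, sp, outgroup = "OUT")
  expect_equal(tab$gene, c("g1", "g2", "g3"))
  expect_equal(tab$concordance, rep(1, 3)) # shared topology by construction
  expect_lt(tab$rtt_variance[1], 1e-15)    # strict clock gene

  for (i in seq_len(nrow(tab))) {
    tr <- root_by_outgroup(genes[[tab$gene[i]]], "OUT")
    expect_equal(tab$concordance[i],
                 concordance_proportion(tr, sp)$concordance)
    st <- tree_stats(prune_taxa(tr, "OUT"))
    expect_equal(tab$rtt_variance[i], st$rtt_variance)
    expect_equal(tab$tree_length[i], st$tree_length)
  }
})

test_that("genes with missing taxa are flagged and unrootable genes skipped", {
  sp <- fixture_species_tree_for_tests(10, 0.5, seed = 63)
  g1 <- apply_rates(sp, rate_decoration("strict"))
  g2 <- prune_taxa(g1, "t3") # one ingroup taxon missing
  g3 <- prune_taxa(g1, setdiff(g1$tip.label, c("t1", "t2", "t4")),
                   min_tips = 3) # no outgroup left -> unrootable
  expect_warning(
    tab <- compute_gene_stats(list(a = g1, b = g2, c = g3), sp,
                              outgroup = "OUT"),
    "skipping gene c")
  expect_equal(tab$gene, c("a", "b"))
  expect_false(tab$missing_taxa[1])
  expect_true(tab$missing_taxa[2])
  st <- tree_stats(prune_taxa(root_by_outgroup(g2, "OUT"), "OUT"))
  expect_equal(tab$rtt_variance[2], st$rtt_variance)
  expect_equal(attr(tab, "skipped")$gene, "c")

  empty <- compute_gene_stats(list(), sp, outgroup = "OUT")
  expect_equal(nrow(empty), 0L)
})

test_that("selection returns top genes and a gap-free concatenation manifest", {
  recs <- data.frame(gene = sprintf("g%02d", 1:10), concordance = 1,
                     rtt_variance = seq(0.001, 0.01, length.out = 10),
                     tree_length = 2)
  ranked <- rank_genes(recs)
  sel <- select_genes(ranked, 3,
                      alignment_lengths = setNames(rep(1500L, 10),
                                                   recs$gene))
  expect_equal(nrow(sel), 3L)
  man <- attr(sel, "manifest")
  expect_equal(man$start, c(1L, 1501L, 3001L))
  expect_equal(man$end, c(1500L, 3000L, 4500L))
  expect_true(all(man$start[-1] == head(man$end, -1) + 1L)) # exact tiling

  expect_warning(all10 <- select_genes(ranked, 99), "returning all")
  expect_equal(nrow(all10), 10L)
})

test_that("shopped genes are more clock-like than random subsets on average", {
  set.seed(64)
  n_pools <- 100
  adv <- numeric(n_pools)
  for (p in seq_len(n_pools)) {
    vars <- rlnorm(20, -6, 1.5)
    recs <- data.frame(gene = sprintf("g%02d", 1:20), concordance = 1,
                       rtt_variance = vars, tree_length = 2)
    shopped <- rank_genes(recs)$rtt_variance[1:3]
    random <- sample(vars, 3)
    adv[p] <- mean(random) - mean(shopped)
  }
  expect_gt(mean(adv), 0)
})

test_that("combining tables joins on the gene column", {
  a <- data.frame(gene = c("g2", "g1"), tree_length = c(2, 1),
                  rtt_variance = c(0.2, 0.1))
  b <- data.frame(gene = c("g1", "g2", "g3"), concordance = c(1, 0.5, 0))
  m <- combine_gene_tables(a, b)
  expect_equal(m$gene, c("g1", "g2"))
  expect_equal(m$concordance, c(1, 0.5))
  expect_equal(names(m), c("gene", "tree_length", "rtt_variance",
                           "concordance"))
})
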