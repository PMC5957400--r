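new_report <- function(name, config, results, summary) {
  structure(list(name = name, config = config, results = results,
                 summary = summary),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment:", x$name, "\n")
  cfg <- x$config[vapply(x$config, function(v) is.atomic(v) &&
                           length(v) <= 8, TRUE)]
  for (nm in names(cfg))
    cat(" ", nm, "=", paste(format(cfg[[nm]]), collapse = ","), "\n")
  cat("  replicates:", nrow(x$results), "\n")
  for (nm in names(x$summary))
    if (is.numeric(x$summary[[nm]]) && length(x$summary[[nm]]) == 1L)
      cat(" ", nm, "=", format(x$summary[[nm]], digits = 5), "\n")
  invisible(x)
}

#' Internal node heights of a rooted tree
#'
#' Heights above the tips (tree height minus node depth), named by the
#' canonical key of the tip set below each internal node.
#'
#' @param tree rooted `phylo`.
#' @return named numeric vector, one entry per internal node.
#' @export
node_heights <- function(tree) {
  nTip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(nTip)]) - depth[(nTip + 1):(nTip + tree$Nnode)]
  clades <- ape::prop.part(tree)
  names(h) <- vapply(clades, function(cl) split_key(tree$tip.label[cl]), "")
  h
}

#' Node-age error between a true and an estimated chronogram
#'
#' The estimated tree's root height is first rescaled to the true root
#' height; the error is then the per-node absolute difference in node age
#' between the two ultrametric trees (matched by the tip set below each
#' node; both trees must resolve the same clades) and its cumulative sum.
#'
#' @param true_tree,estimated_tree ultrametric `phylo` objects on the same
#'   taxa with the same topology.
#' @return list with `per_node` (named absolute differences), `total`
#'   (cumulative sum), `n_nodes`.
#' @export
dating_error <- function(true_tree, estimated_tree) {
  ht <- node_heights(true_tree)
  he <- node_heights(estimated_tree)
  if (!setequal(names(ht), names(he)))
    stop("trees do not share the same clades; dating error requires a ",
         "fixed shared topology")
  he <- he[names(ht)]
  scale <- max(ht) / max(he) # rescale estimate's root height to the truth

  d <- abs(ht - he * scale)
  list(per_node = d, total = sum(d), n_nodes = length(d))
}

#' Clock-test false-rejection experiment
#'
#' Simulates alignments under a strict clock on a fixed ultrametric tree
#' (so the clock null is true by construction) and records how often the
#' strict-clock likelihood-ratio test rejects at level `alpha`. With
#' matched simulation and test models the empirical rate estimates the
#' test's type-I error.
#'
#' @param tree ultrametric `phylo` (the strict-clock truth).
#' @param model a [subst_model] used both to simulate and to test.
#' @param length alignment length in sites.
#' @param n_reps number of replicate alignments.
#' @param alpha significance level.
#' @param seed optional integer seed making the report reproducible.
#' @return an `experiment_report`; `$results` has one row per replicate
#'   (statistic, p_value, rejected), `$summary` the empirical
#'   `rejection_rate` with a 95% binomial confidence interval. Failed
#'   replicates are recorded and excluded from the denominator.
#' @export
false_rejection_experiment <- function(tree, model = poisson_model(),
                                       length = 500L, n_reps = 500L,
                                       alpha = 0.05, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_reps >= 1)
  if (!is_ultrametric(tree, tol = 1e-6))
    stop("the generating tree must be ultrametric (strict-clock truth)")
  with_seed(seed, {
    rows <- vector("list", n_reps)
    for (i in seq_len(n_reps)) {
      rows[[i]] <- tryCatch({
        aln <- simulate_alignment(tree, model, length)
        r <- clock_lrt(aln, tree, model, alpha = alpha)
        data.frame(rep = i, statistic = r$statistic, df = r$df,
                   p_value = r$p_value, rejected = r$rejected, ok = TRUE)
      }, error = function(e) data.frame(rep = i, statistic = NA_real_,
                                        df = NA_integer_, p_value = NA_real_,
                                        rejected = NA, ok = FALSE))
    }
    res <- do.call(rbind, rows)
    ok <- res[res$ok, , drop = FALSE]
    bt <- stats::binom.test(sum(ok$rejected), nrow(ok))
    new_report(
      "false_rejection",
      list(n_taxa = ape::Ntip(tree), model = model$name, length = length,
           n_reps = n_reps, alpha = alpha, seed = seed),
      res,
      list(rejection_rate = mean(ok$rejected), n_ok = nrow(ok),
           n_failed = n_reps - nrow(ok),
           ci_low = bt$conf.int[1], ci_high = bt$conf.int[2]))
  })
}

#' Maximum-likelihood strict-clock dating on a fixed topology
#'
#' Joint ML estimation of relative node ages for one or more gene
#' alignments sharing a single molecular clock, each with its own relative
#' rate: branch lengths for gene g are `rate[g] * (parent height - child
#' height)` on one shared set of node heights. The root height is fixed at
#' 1 (rates absorb the scale), so the result is a chronogram in relative
#' ages. Heights use the same proportion parameterization as
#' [optimize_clock()]; height and rate coordinates are swept alternately.
#'
#' @param alignments a [phangorn::phyDat] or list of them (the genes).
#' @param topology rooted `phylo` to date; branch lengths, if any, only
#'   seed the initial heights.
#' @param model a [subst_model]; inferred per alignment when `NULL`.
#' @param tol convergence tolerance on the joint log-likelihood.
#' @param max_rounds maximum sweeps (warning on non-convergence).
#' @return list with `tree` (ultrametric, root height 1), `rates` (per-gene
#'   relative rates), `logLik`, `rounds`, `converged`.
#' @export
strict_clock_ml_dating <- function(alignments, topology, model = NULL,
                                   tol = 1e-6, max_rounds = 25L) {
  if (inherits(alignments, "phyDat")) alignments <- list(alignments)
  stopifnot(length(alignments) >= 1L, inherits(topology, "phylo"),
            ape::is.rooted(topology))
  if (is.null(topology$edge.length) || tree_height(topology) <= 0)
    topology$edge.length <- rep(1, nrow(topology$edge))
  ds <- lapply(alignments, tree_lik_data, tree = topology, model = model)
  tr <- ds[[1]]$tree
  nTip <- ds[[1]]$nTip
  nNode <- ds[[1]]$nNode
  root <- nTip + 1L
  parent_of <- integer(nNode)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  pre <- c(root, rev(tr$edge[tr$edge[, 2] > nTip, 2]))
  h0 <- init_heights(tr)
  h0 <- h0 / h0[root]
  prop <- numeric(nNode)
  for (v in pre) prop[v] <- if (v == root) 1 else h0[v] / h0[parent_of[v]]
  heights_of <- function(prop) {
    h <- numeric(nNode)
    h[root] <- 1
    for (v in pre) if (v != root) h[v] <- prop[v] * h[parent_of[v]]
    h
  }
  G <- length(ds)
  rates <- rep(tree_height(topology), G)
  gene_lnL <- function(g, el) plik_full(ds[[g]]$edge, el, nTip, nNode,
                                        ds[[g]]$tip_idx, ds[[g]]$contrast,
                                        ds[[g]]$weight, ds[[g]]$k)
  total_lnL <- function(prop, rates) {
    el0 <- heights_to_el(tr, heights_of(prop))
    sum(vapply(seq_len(G), function(g) gene_lnL(g, rates[g] * el0), 0))
  }
  lnL <- total_lnL(prop, rates)
  rounds <- 0L
  converged <- FALSE
  # bulk quasi-Newton stage over (proportions, per-gene rates); gradients
  # come from the per-branch derivatives by the chain rule (root fixed at 1)
  nedge <- nrow(tr$edge)
  stem_of <- integer(nNode)
  stem_of[tr$edge[, 2]] <- seq_len(nedge)
  free_nodes <- setdiff(pre, root)
  nfree <- length(free_nodes)
  date_fn <- function(par) {
    prop[free_nodes] <- par[seq_len(nfree)]
    -total_lnL(prop, par[-seq_len(nfree)])
  }
  date_gr <- function(par) {
    prop[free_nodes] <- par[seq_len(nfree)]
    rr <- par[-seq_len(nfree)]
    h <- heights_of(prop)
    el0 <- heights_to_el(tr, h)
    g0 <- numeric(nedge) # d lnL / d el0 summed over genes
    grates <- numeric(G)
    for (g in seq_len(G)) {
      r <- plik_grad(ds[[g]]$edge, rr[g] * el0, nTip, nNode,
                     ds[[g]]$tip_idx, ds[[g]]$contrast, ds[[g]]$weight,
                     ds[[g]]$k)
      g0 <- g0 + r$grad * rr[g]
      grates[g] <- sum(r$grad * el0)
    }
    gt <- g0 * el0
    A <- numeric(nNode)
    for (e in seq_len(nedge)) {
      p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
      A[p] <- A[p] + gt[e] + A[c]
    }
    gprop <- (A[free_nodes] - g0[stem_of[free_nodes]] * h[free_nodes]) /
      prop[free_nodes]
    -c(gprop, grates)
  }
  opt <- try(stats::optim(c(prop[free_nodes], rates), date_fn, date_gr,
                          method = "L-BFGS-B",
                          lower = c(rep(1e-9, nfree), rep(1e-8, G)),
                          upper = c(rep(1 - 1e-9, nfree), rep(Inf, G)),
                          control = list(maxit = 200L, factr = 1e7)),
             silent = TRUE)
  if (!inherits(opt, "try-error") && -opt$value >= lnL) {
    prop[free_nodes] <- opt$par[seq_len(nfree)]
    rates <- opt$par[-seq_len(nfree)]
    lnL <- -opt$value
  }
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    el0 <- heights_to_el(tr, heights_of(prop))
    for (g in seq_len(G)) { # profile each gene's relative rate
      hi <- 4 * max(rates[g], 0.05)
      for (try in 1:6) {
        opt <- stats::optimize(function(r) -gene_lnL(g, r * el0),
                               interval = c(1e-8, hi), tol = 1e-6 * hi)
        if (opt$minimum < 0.95 * hi) break
        hi <- 2 * hi
      }
      if (-opt$objective >= gene_lnL(g, rates[g] * el0))
        rates[g] <- opt$minimum
    }
    for (v in pre) { # shared node heights
      if (v == root) next
      f <- function(x) { pp <- prop; pp[v] <- x; -total_lnL(pp, rates) }
      opt <- stats::optimize(f, interval = c(1e-9, 1 - 1e-9), tol = 1e-5)
      if (-opt$objective >= -f(prop[v])) prop[v] <- opt$minimum
    }
    new <- total_lnL(prop, rates)
    if (new - lnL < tol) {
      lnL <- max(new, lnL)
      converged <- TRUE
      break
    }
    lnL <- new
  }
  if (!converged)
    warning("strict-clock dating did not converge in ", max_rounds,
            " sweeps; returning best estimate")
  out <- tr
  out$edge.length <- heights_to_el(tr, heights_of(prop))
  list(tree = out, rates = rates, logLik = lnL, rounds = rounds,
       converged = converged)
}

#' Shopped versus random gene selection for dating
#'
#' The headline validation: per trial, one Yule chronogram is simulated; a
#' pool of genes evolves on it under a strict clock with gene-specific
#' rates and per-branch Gaussian noise (noise level drawn per gene from
#' `noise_grid`); per-gene ML phylograms are estimated on the fixed true
#' topology; two three-gene datasets are built (winnowing-ranked top genes
#' versus a uniform random draw) and each is dated by
#' [strict_clock_ml_dating()]; node-age error against the true chronogram
#' (after root rescaling) is recorded per arm.
#'
#' @param n_trials number of independent trials.
#' @param n_taxa taxa per Yule tree.
#' @param root_height height each Yule chronogram is rescaled to (time
#'   units) before rates are applied, keeping substitution branch lengths
#'   in an identifiable regime.
#' @param n_genes gene-pool size per trial.
#' @param n_select genes per dataset (both arms).
#' @param noise_grid noisy-clock noise standard deviations sampled
#'   uniformly per gene.
#' @param rate_range range of the per-gene global rate (uniform draw),
#'   giving the pool its tree-length heterogeneity.
#' @param length alignment length in sites.
#' @param model a [subst_model].
#' @param seed optional integer seed.
#' @return an `experiment_report`; `$results` has one row per trial with
#'   `error_shopped` and `error_random` (cumulative node-age error per
#'   arm), `$summary` medians per arm and a one-sided paired Wilcoxon
#'   p-value for shopped < random.
#' @export
shopping_vs_random_experiment <- function(n_trials = 50L, n_taxa = 12L,
                                          root_height = 0.5,
                                          n_genes = 200L, n_select = 3L,
                                          noise_grid = c(0, 0.1, 0.25, 0.5,
                                                         0.75),
                                          rate_range = c(0.5, 1.5),
                                          length = 1500L,
                                          model = jc_model(), seed = NULL) {
  stopifnot(n_genes >= 10 * n_select)
  with_seed(seed, {
    rows <- vector("list", n_trials)
    for (trial in seq_len(n_trials)) {
      rows[[trial]] <- tryCatch({
        chrono <- rescale_height(simulate_yule(n_taxa, 1), root_height)
        noises <- sample(noise_grid, n_genes, replace = TRUE)
        grates <- stats::runif(n_genes, rate_range[1], rate_range[2])
        alns <- vector("list", n_genes)
        gtrees <- vector("list", n_genes)
        for (j in seq_len(n_genes)) {
          dec <- rate_decoration("noisy_clock", rate = grates[j],
                                 noise_sd = noises[j])
          phy <- apply_rates(chrono, dec)
          alns[[j]] <- simulate_alignment(phy, model, length)
          gtrees[[j]] <- optimize_free(alns[[j]], chrono, model,
                                       tol = 0.01)$tree
        }
        ids <- sprintf("g%04d", seq_len(n_genes))
        names(alns) <- names(gtrees) <- ids
        stats_tab <- compute_gene_stats(gtrees, chrono)
        ranked <- rank_genes(stats_tab)
        shopped <- ranked$gene[seq_len(n_select)]
        random <- sample(ids, n_select)
        date_arm <- function(sel) {
          fit <- strict_clock_ml_dating(alns[sel], chrono, model, tol = 1e-4)
          dating_error(chrono, fit$tree)$total
        }
        data.frame(trial = trial,
                   error_shopped = date_arm(shopped),
                   error_random = date_arm(random),
                   mean_noise_shopped = mean(noises[match(shopped, ids)]),
                   mean_noise_random = mean(noises[match(random, ids)]),
                   ok = TRUE)
      }, error = function(e) {
        warning("trial ", trial, " failed: ", conditionMessage(e),
                call. = FALSE)
        data.frame(trial = trial, error_shopped = NA_real_,
                   error_random = NA_real_, mean_noise_shopped = NA_real_,
                   mean_noise_random = NA_real_, ok = FALSE)
      })
    }
    res <- do.call(rbind, rows)
    ok <- res[res$ok, , drop = FALSE]
    wt <- if (all(ok$error_shopped == ok$error_random)) NULL else
      stats::wilcox.test(ok$error_shopped, ok$error_random, paired = TRUE,
                         alternative = "less", exact = FALSE)
    new_report(
      "shopping_vs_random",
      list(n_trials = n_trials, n_taxa = n_taxa,
           root_height = root_height, n_genes = n_genes,
           n_select = n_select, noise_grid = noise_grid,
           rate_range = rate_range, length = length, model = model$name,
           seed = seed),
      res,
      list(median_error_shopped = stats::median(ok$error_shopped),
           median_error_random = stats::median(ok$error_random),
           p_shopped_less = if (is.null(wt)) NA_real_ else wt$p.value,
           n_ok = nrow(ok), n_failed = n_trials - nrow(ok)))
  })
}

#' Rate-heterogeneity landscape of gene-tree pools
#'
#' Summarizes pools of phylograms (e.g. simulated clock, noisy-clock and
#' UCLN genes, or an empirical gene set) as the scatter of (tree length,
#' root-to-tip variance) per gene plus per-tip deviations from each gene's
#' mean root-to-tip path — the raw material of clock-likeness landscapes.
#'
#' @param pools named list of conditions, each a list of rooted `phylo`
#'   phylograms.
#' @return an `experiment_report`; `$results` has one row per gene
#'   (condition, gene, tree_length, rtt_variance), `$summary` per-condition
#'   medians, and element `deviations` of the report holds per-tip
#'   deviations (condition, gene, tip, deviation).
#' @export
heterogeneity_landscape <- function(pools) {
  stopifnot(is.list(pools), length(pools) >= 1L, !is.null(names(pools)))
  rows <- list()
  devs <- list()
  for (cond in names(pools)) {
    trees <- pools[[cond]]
    for (j in seq_along(trees)) {
      st <- tree_stats(trees[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, gene = j, tree_length = st$tree_length,
        rtt_variance = st$rtt_variance)
      devs[[length(devs) + 1L]] <- data.frame(
        condition = cond, gene = j, tip = names(st$rtt_deviations),
        deviation = unname(st$rtt_deviations))
    }
  }
  res <- do.call(rbind, rows)
  med <- lapply(split(res, res$condition), function(d)
    c(median_tree_length = stats::median(d$tree_length),
      median_rtt_variance = stats::median(d$rtt_variance)))
  rep <- new_report("heterogeneity_landscape",
                    list(conditions = names(pools),
                         n_trees = vapply(pools, length, 0L)),
                    res, med)
  rep$deviations <- do.call(rbind, devs)
  rep
}
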