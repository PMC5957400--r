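# Assemble the data the C engine consumes: postorder edge matrix, branch
# lengths, tip pattern indices in tip order, contrast matrix, weights.
tree_lik_data <- function(aln, tree, model = NULL) {
  stopifnot(inherits(aln, "phyDat"), inherits(tree, "phylo"))
  model <- default_model(aln, model)
  only_tree <- setdiff(tree$tip.label, names(aln))
  only_aln <- setdiff(names(aln), tree$tip.label)
  if (length(only_tree) || length(only_aln))
    stop("taxon mismatch between tree and alignment; tree-only: {",
         paste(only_tree, collapse = ", "), "}, alignment-only: {",
         paste(only_aln, collapse = ", "), "}")
  tree <- validate_tree(tree)
  tr <- stats::reorder(tree, "postorder")
  list(tree = tr,
       edge = tr$edge,
       el = tr$edge.length,
       nTip = ape::Ntip(tr),
       nNode = ape::Ntip(tr) + tr$Nnode,
       tip_idx = unname(aln[tr$tip.label]),
       contrast = attr(aln, "contrast"),
       weight = as.numeric(attr(aln, "weight")),
       k = model$k)
}

#' Pruning-algorithm log-likelihood
#'
#' Exact Felsenstein-pruning log-likelihood of an alignment on a tree under
#' a symmetric substitution model ([subst_model]). Gaps and ambiguity codes
#' contribute partial likelihoods of one (missing data). The value is
#' independent of root placement (the model is time-reversible).
#'
#' @param aln a [phangorn::phyDat] alignment.
#' @param tree a `phylo` whose tips match the alignment's taxa.
#' @param model a [subst_model]; inferred from the alphabet when `NULL`.
#' @return the log-likelihood (numeric scalar).
#' @examples
#' tr <- read_newick("(a:0.05,b:0.05);")
#' aln <- simulate_alignment(tr, jc_model(), length = 100, seed = 1)
#' log_likelihood(aln, tr)
#' @export
log_likelihood <- function(aln, tree, model = NULL) {
  d <- tree_lik_data(aln, tree, model)
  plik_full(d$edge, d$el, d$nTip, d$nNode, d$tip_idx, d$contrast, d$weight,
            d$k)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate ascent over branch lengths: each branch in turn is optimized
#' by bounded scalar optimization (Brent) with the partial likelihoods of
#' the rest of the tree cached, sweeping until the log-likelihood improves
#' by less than `tol`. On a rooted topology only the sum of the two root
#' branches is identifiable; their split is arbitrary.
#'
#' @inheritParams log_likelihood
#' @param max_edge upper bound per branch (expected substitutions/site).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_rounds maximum number of sweeps; a warning is issued if the
#'   fit has not converged by then.
#' @return list with `tree` (branch lengths replaced by their ML values),
#'   `logLik`, `rounds`, `converged`.
#' @export
optimize_free <- function(aln, tree, model = NULL, max_edge = 10,
                          tol = 1e-6, max_rounds = 50L) {
  d <- tree_lik_data(aln, tree, model)
  el <- pmin(pmax(d$el, 1e-8), max_edge)
  if (all(el <= 1e-8)) el[] <- 0.05
  nedge <- nrow(d$edge)
  lnL <- plik_full(d$edge, el, d$nTip, d$nNode, d$tip_idx, d$contrast,
                   d$weight, d$k)
  rounds <- 0L
  converged <- FALSE
  full <- function(el) plik_full(d$edge, el, d$nTip, d$nNode, d$tip_idx,
                                 d$contrast, d$weight, d$k)
  # cheap global rescaling first: starting lengths are often off by a
  # common factor (e.g. a gene-specific rate), which one Brent fit absorbs
  sc <- stats::optimize(function(s) -full(pmin(s * el, max_edge)),
                        interval = c(0.02, 50), tol = 1e-3)
  if (-sc$objective > lnL) {
    el <- pmin(sc$minimum * el, max_edge)
    lnL <- -sc$objective
  }
  # gradient-assisted bulk move next: L-BFGS-B evaluates the objective and
  # gradient in pairs, so one memoized pruning+gradient pass serves both
  memo <- new.env(parent = emptyenv())
  fg <- function(p) {
    if (is.null(memo$p) || !identical(memo$p, p)) {
      memo$p <- p
      memo$v <- plik_grad(d$edge, p, d$nTip, d$nNode, d$tip_idx,
                          d$contrast, d$weight, d$k)
    }
    memo$v
  }
  opt <- try(stats::optim(el, function(p) -fg(p)$lnl,
                          function(p) -fg(p)$grad,
                          method = "L-BFGS-B", lower = 1e-9,
                          upper = max_edge,
                          control = list(
                            maxit = 100L,
                            factr = max(1e7, 0.1 * tol /
                                          (2.2e-16 * max(1, abs(lnL)))))),
             silent = TRUE)
  if (!inherits(opt, "try-error") && -opt$value >= lnL) {
    el <- opt$par
    lnL <- -opt$value
  }
  # finish with per-branch Brent sweeps until a full sweep improves the
  # log-likelihood by less than `tol`; a sweep normally reuses one partial
  # cache, and falls back to refreshing the cache per edge whenever the
  # shared-cache sweep fails to improve
  brent_tol <- max(1e-7, 0.01 * tol)
  exact_confirm <- tol < 0.01 # loose fits may stop on a shared-cache sweep
  sweep_edges <- function(el, per_edge_cache) {
    cache <- NULL
    for (e in seq_len(nedge)) {
      if (is.null(cache) || per_edge_cache)
        cache <- plik_cache(d$edge, el, d$nTip, d$nNode, d$tip_idx,
                            d$contrast, d$weight, d$k)
      f <- function(t) -plik_edge(t, e - 1L, d$edge, d$nTip, cache$lowers,
                                  cache$lls, cache$uppers, cache$uls,
                                  d$weight, d$k)
      opt <- stats::optimize(f, interval = c(0, max_edge), tol = brent_tol)
      if (-opt$objective >= -f(el[e])) el[e] <- opt$minimum
    }
    el
  }
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    el_try <- sweep_edges(el, per_edge_cache = FALSE)
    new <- full(el_try)
    if (new < lnL + tol && exact_confirm) {
      el_try <- sweep_edges(el, per_edge_cache = TRUE)
      new <- full(el_try)
    }
    if (new >= lnL) el <- el_try
    if (new - lnL < tol) {
      lnL <- max(new, lnL)
      converged <- TRUE
      break
    }
    lnL <- new
  }
  if (!converged)
    warning("branch-length optimization did not converge in ", max_rounds,
            " sweeps; returning best fit so far")
  out <- d$tree
  out$edge.length <- el
  list(tree = out, logLik = lnL, rounds = rounds, converged = converged)
}

# Internal-node heights from a (possibly non-ultrametric) rooted tree,
# made strictly monotone parent > child. Tips sit at height 0.
init_heights <- function(tree) {
  nTip <- ape::Ntip(tree)
  nNode <- nTip + tree$Nnode
  depth <- ape::node.depth.edgelength(tree)
  h <- numeric(nNode)
  scale <- max(depth[seq_len(nTip)])
  if (scale <= 0) scale <- 1
  h[(nTip + 1):nNode] <- mean(depth[seq_len(nTip)]) - depth[(nTip + 1):nNode]
  tr <- stats::reorder(tree, "postorder")
  eps <- 1e-6 * scale
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
    h[p] <- max(h[p], h[c] + eps)
  }
  h
}

heights_to_el <- function(tree, h) {
  h[tree$edge[, 1]] - h[tree$edge[, 2]]
}

#' Maximum-likelihood clock tree on a fixed rooted topology
#'
#' Optimizes the n-1 internal-node heights of a rooted topology under a
#' strict clock (branch length = parent height minus child height, tips at
#' height 0). Heights are parameterized as the root height plus, per
#' internal node, its height as a proportion of its parent's, so the
#' monotonicity constraint is a simple box and moving one parameter
#' rescales the whole subtree beneath it. A box-constrained quasi-Newton
#' stage (analytic gradient via the chain rule from per-branch derivatives)
#' does the bulk of the work; per-parameter bounded scalar sweeps (Brent)
#' then finish the fit, and convergence is declared when a full sweep
#' improves the log-likelihood by less than `tol`. The returned tree is
#' ultrametric and its log-likelihood never exceeds the free-branch-length
#' maximum.
#'
#' @inheritParams optimize_free
#' @param tree a rooted `phylo` (the clock-constrained topology).
#' @param start_heights optional starting node heights (indexed by node id,
#'   tips at 0), e.g. from a free-branch-length fit.
#' @return list with `tree` (ultrametric), `logLik`, `heights` (per-node,
#'   tips at 0), `rounds`, `converged`.
#' @export
optimize_clock <- function(aln, tree, model = NULL, tol = 1e-6,
                           max_rounds = 25L, start_heights = NULL) {
  if (!ape::is.rooted(tree)) stop("clock optimization requires a rooted tree")
  d <- tree_lik_data(aln, tree, model)
  tr <- d$tree
  nTip <- d$nTip
  root <- nTip + 1L
  internals <- (nTip + 1L):d$nNode
  parent_of <- integer(d$nNode)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  # preorder over internal nodes (parents before children): the edge matrix
  # is postorder, so reversed child ids visit parents first
  pre <- c(root, rev(tr$edge[tr$edge[, 2] > nTip, 2]))
  h0 <- if (is.null(start_heights)) init_heights(tr) else start_heights
  H <- h0[root]
  prop <- numeric(d$nNode)
  for (v in pre) prop[v] <- if (v == root) 1 else h0[v] / h0[parent_of[v]]
  heights_of <- function(H, prop) {
    h <- numeric(d$nNode)
    h[root] <- H
    for (v in pre) if (v != root) h[v] <- prop[v] * h[parent_of[v]]
    h
  }
  lnL_of <- function(H, prop) plik_full(
    d$edge, heights_to_el(tr, heights_of(H, prop)), nTip, d$nNode,
    d$tip_idx, d$contrast, d$weight, d$k)
  lnL <- lnL_of(H, prop)
  rounds <- 0L
  converged <- FALSE
  pmax_ <- 1 - 1e-9
  # bulk gradient stage: d lnL/d t_e from the partial caches, mapped by the
  # chain rule onto the root height (all branches scale) and each
  # proportion (its subtree scales, its stem shrinks)
  nedge <- nrow(tr$edge)
  stem_of <- integer(d$nNode)
  stem_of[tr$edge[, 2]] <- seq_len(nedge)
  free_nodes <- setdiff(pre, root)
  clock_fg <- function(par) {
    H <- par[1]
    prop[free_nodes] <- par[-1]
    h <- heights_of(H, prop)
    el <- heights_to_el(tr, h)
    r <- plik_grad(d$edge, el, nTip, d$nNode, d$tip_idx, d$contrast,
                   d$weight, d$k)
    gt <- r$grad * el
    A <- numeric(d$nNode)
    for (e in seq_len(nedge)) { # postorder: children accumulated first
      p <- tr$edge[e, 1]; c <- tr$edge[e, 2]
      A[p] <- A[p] + gt[e] + A[c]
    }
    gpar <- c(A[root] / H,
              (A[free_nodes] - r$grad[stem_of[free_nodes]] *
                 h[free_nodes]) / prop[free_nodes])
    list(lnl = r$lnl, grad = gpar)
  }
  clock_fn <- function(par) {
    prop[free_nodes] <- par[-1]
    -lnL_of(par[1], prop)
  }
  opt <- try(stats::optim(c(H, prop[free_nodes]),
                          clock_fn, function(p) -clock_fg(p)$grad,
                          method = "L-BFGS-B",
                          lower = c(1e-8, rep(1e-9, length(free_nodes))),
                          upper = c(Inf, rep(pmax_, length(free_nodes))),
                          control = list(maxit = 100L, factr = 1e7)),
             silent = TRUE)
  if (!inherits(opt, "try-error") && -opt$value >= lnL) {
    H <- opt$par[1]
    prop[free_nodes] <- opt$par[-1]
    lnL <- -opt$value
  }
  # exact per-parameter sweeps finish the fit
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    # root height: bounded scalar optimization with interval growth
    hi <- 4 * H
    for (try in 1:6) {
      opt <- stats::optimize(function(x) -lnL_of(x, prop),
                             interval = c(1e-8, hi), tol = 1e-7 + 1e-6 * hi)
      if (opt$minimum < 0.95 * hi) break
      hi <- 2 * hi
    }
    if (-opt$objective >= lnL_of(H, prop)) H <- opt$minimum
    for (v in pre) {
      if (v == root) next
      f <- function(x) { pp <- prop; pp[v] <- x; -lnL_of(H, pp) }
      opt <- stats::optimize(f, interval = c(1e-9, pmax_), tol = 1e-5)
      if (-opt$objective >= -f(prop[v])) prop[v] <- opt$minimum
    }
    new <- lnL_of(H, prop)
    if (new - lnL < tol) {
      lnL <- max(new, lnL)
      converged <- TRUE
      break
    }
    lnL <- new
  }
  if (!converged)
    warning("clock optimization did not converge in ", max_rounds, " sweeps")
  h <- heights_of(H, prop)
  out <- tr
  out$edge.length <- heights_to_el(tr, h)
  list(tree = out, logLik = lnL, heights = h, rounds = rounds,
       converged = converged)
}

#' Strict-clock likelihood-ratio test
#'
#' The standard molecular-clock test: the alignment's ML score is computed
#' on the given rooted topology both with free branch lengths and under a
#' strict clock, and twice the log-likelihood difference is compared to a
#' chi-square distribution with n - 2 degrees of freedom (2n - 3 free
#' branch lengths versus n - 1 clock node heights for n taxa). Outgroups
#' should be pruned beforehand.
#'
#' @inheritParams optimize_clock
#' @param alpha significance level for the rejection flag.
#' @return object of class `clock_test`: list with `lnL_free`, `lnL_clock`,
#'   `statistic`, `df`, `p_value`, `rejected`, `alpha`.
#' @examples
#' tr <- read_newick("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
#' aln <- simulate_alignment(tr, jc_model(), length = 500, seed = 7)
#' clock_lrt(aln, tr)
#' @export
clock_lrt <- function(aln, tree, model = NULL, alpha = 0.05, tol = 1e-6) {
  free <- optimize_free(aln, tree, model, tol = tol)
  clk <- optimize_clock(aln, tree, model, tol = tol,
                        start_heights = init_heights(free$tree))
  stat <- max(0, 2 * (free$logLik - clk$logLik))
  df <- ape::Ntip(tree) - 2L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  out <- list(lnL_free = free$logLik, lnL_clock = clk$logLik,
              statistic = stat, df = df, p_value = p,
              rejected = p < alpha, alpha = alpha)
  class(out) <- "clock_test"
  out
}

#' @export
print.clock_test <- function(x, ...) {
  cat(sprintf(
    "strict-clock LRT: lnL_free %.4f  lnL_clock %.4f  2dL %.4f  df %d  p %.4g%s\n",
    x$lnL_free, x$lnL_clock, x$statistic, x$df, x$p_value,
    if (x$rejected) sprintf("  [clock rejected at %g]", x$alpha) else ""))
  invisible(x)
}
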