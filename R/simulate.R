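with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a Yule (pure-birth) chronogram
#'
#' Forward simulation from two lineages: with k extant lineages the waiting
#' time to the next speciation is exponential with rate k*lambda, and the
#' splitting lineage is chosen uniformly. Simulation stops at the birth of
#' the n-th lineage, so the root height (no origin stem) is a sum of
#' exponentials with expectation sum_{k=2}^{n-1} 1/(k*lambda). The result is
#' ultrametric with tips labelled `t1..tn`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param speciation_rate per-lineage speciation rate lambda (> 0).
#' @param seed optional integer seed; when given the caller's RNG state is
#'   left untouched and the output is a deterministic function of the seed.
#' @return an ultrametric `phylo`.
#' @examples
#' tr <- simulate_yule(12, 1, seed = 42)
#' is_ultrametric(tr)
#' @export
simulate_yule <- function(n_taxa, speciation_rate = 1, seed = NULL) {
  stopifnot(n_taxa >= 2, speciation_rate > 0)
  with_seed(seed, {
    n <- as.integer(n_taxa)
    if (n == 2L) { # degenerate: one waiting time at k = 2, then cut
      h <- stats::rexp(1, rate = 2 * speciation_rate)
      return(read_newick(sprintf("(t1:%.17g,t2:%.17g);", h, h)))
    }
    # active lineages: parent internal node (final ape id) and start time
    par <- c(n + 1L, n + 1L)
    start <- c(0, 0)
    next_int <- n + 2L
    t <- 0
    edge_p <- integer(0); edge_c <- integer(0); edge_l <- numeric(0)
    while (length(par) < n) {
      k <- length(par)
      t <- t + stats::rexp(1, rate = k * speciation_rate)
      j <- sample.int(k, 1)
      m <- next_int; next_int <- next_int + 1L
      edge_p <- c(edge_p, par[j]); edge_c <- c(edge_c, m)
      edge_l <- c(edge_l, t - start[j])
      par <- c(par[-j], m, m)
      start <- c(start[-j], t, t)
    }
    edge_p <- c(edge_p, par); edge_c <- c(edge_c, seq_len(n))
    edge_l <- c(edge_l, t - start)
    tr <- list(edge = cbind(edge_p, edge_c, deparse.level = 0),
               edge.length = edge_l,
               tip.label = paste0("t", seq_len(n)),
               Nnode = n - 1L)
    class(tr) <- "phylo"
    stats::reorder(tr) # ape's canonical cladewise order
  })
}

#' Rescale a tree to a target root height
#'
#' Multiplies every branch length by `target_height / current_height`.
#' Ultrametricity is preserved.
#'
#' @param tree rooted `phylo` with positive height.
#' @param target_height desired maximum root-to-tip path length.
#' @return the rescaled `phylo`.
#' @export
rescale_height <- function(tree, target_height) {
  stopifnot(inherits(tree, "phylo"), target_height > 0)
  h <- tree_height(tree)
  if (h <= 0) stop("cannot rescale a zero-height tree")
  tree$edge.length <- tree$edge.length * (target_height / h)
  if (!is.null(tree$root.edge))
    tree$root.edge <- tree$root.edge * (target_height / h)
  tree
}

#' Branch-rate models (strict clock, noisy clock, UCLN)
#'
#' A rate decoration maps a chronogram (branch lengths in time) to a
#' phylogram (expected substitutions per site) by multiplying each branch by
#' a branch-specific rate:
#' * `strict`: every branch gets `rate`.
#' * `noisy_clock`: `rate` plus a draw from Normal(0, `noise_sd`), redrawn
#'   until positive (negative rates are impossible; the redraw policy
#'   matters once `noise_sd` approaches `rate`).
#' * `ucln`: independent LogNormal(`mean_log`, `stdev_log`) draw per branch
#'   (parameters on the natural-log scale), the uncorrelated lognormal
#'   relaxed clock.
#'
#' @param kind one of `"strict"`, `"noisy_clock"`, `"ucln"`.
#' @param rate global rate (strict and noisy clock), substitutions/site/time.
#' @param noise_sd standard deviation of the zero-mean Gaussian noise
#'   (noisy clock).
#' @param mean_log,stdev_log log-scale parameters of the UCLN lognormal.
#' @return object of class `rate_decoration`.
#' @examples
#' dec <- rate_decoration("ucln", mean_log = -0.5, stdev_log = 0.5)
#' @export
rate_decoration <- function(kind = c("strict", "noisy_clock", "ucln"),
                            rate = 1, noise_sd = 0, mean_log = -0.5,
                            stdev_log = 0.5) {
  kind <- match.arg(kind)
  stopifnot(rate > 0, noise_sd >= 0, stdev_log >= 0)
  structure(list(kind = kind, rate = rate, noise_sd = noise_sd,
                 mean_log = mean_log, stdev_log = stdev_log),
            class = "rate_decoration")
}

draw_rates <- function(decoration, n) {
  switch(decoration$kind,
    strict = rep(decoration$rate, n),
    noisy_clock = {
      if (decoration$noise_sd == 0) rep(decoration$rate, n)
      else {
        r <- decoration$rate + stats::rnorm(n, 0, decoration$noise_sd)
        while (any(bad <- r <= 0))
          r[bad] <- decoration$rate +
            stats::rnorm(sum(bad), 0, decoration$noise_sd)
        r
      }
    },
    ucln = stats::rlnorm(n, decoration$mean_log, decoration$stdev_log))
}

#' Decorate a chronogram with branch rates
#'
#' Multiplies each branch of an ultrametric chronogram by a branch-specific
#' rate drawn from the given [rate_decoration], producing a phylogram. With
#' a strict decoration at rate 1 the phylogram equals the chronogram.
#'
#' @param chronogram ultrametric `phylo`.
#' @param decoration a [rate_decoration].
#' @param seed optional integer seed (see [simulate_yule]).
#' @return a `phylo` phylogram; the per-branch rates are attached as
#'   attribute `rates` (in `$edge` row order).
#' @export
apply_rates <- function(chronogram, decoration, seed = NULL) {
  stopifnot(inherits(chronogram, "phylo"),
            inherits(decoration, "rate_decoration"))
  if (!is_ultrametric(chronogram, tol = 1e-6))
    stop("chronogram must be ultrametric")
  with_seed(seed, {
    r <- draw_rates(decoration, nrow(chronogram$edge))
    out <- chronogram
    out$edge.length <- chronogram$edge.length * r
    attr(out, "rates") <- r
    out
  })
}

#' Simulate an alignment along a phylogram
#'
#' Evolves sequences down the tree under a symmetric model ([subst_model]):
#' root states are drawn from the uniform stationary distribution and
#' propagated through the closed-form transition probabilities (via
#' [phangorn::simSeq()], whose default DNA and AA models are exactly JC and
#' Poisson with mean rate one). Output is gap-free.
#'
#' @param tree `phylo` phylogram (branch lengths in expected
#'   substitutions/site).
#' @param model a [subst_model].
#' @param length number of sites (>= 1).
#' @param seed optional integer seed.
#' @return a [phangorn::phyDat] alignment.
#' @export
simulate_alignment <- function(tree, model = jc_model(), length = 1000L,
                               seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "subst_model"),
            length >= 1)
  with_seed(seed, phangorn::simSeq(tree, l = length, type = model$type))
}
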