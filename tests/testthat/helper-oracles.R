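# Independent oracles used to cross-check the package's implementations.
# These deliberately avoid the code paths they verify.

# Brute-force bipartition enumeration: delete each edge of the unrooted
# topology in turn and read off the tip set of the detached component by
# breadth-first search over an adjacency list.
oracle_splits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  adj <- vector("list", nnode)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  ref <- sort(tr$tip.label)[1]
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    # BFS from b avoiding the removed edge (a,b)
    seen <- rep(FALSE, nnode)
    seen[b] <- TRUE
    queue <- b
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == b && w == a) next
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    side <- tr$tip.label[which(seen[seq_len(ntip)])]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (ref %in% side) side <- setdiff(tr$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  sort(unique(keys))
}

oracle_concordance <- function(gene, species) {
  g <- oracle_splits(gene)
  s <- oracle_splits(species)
  if (length(g) == 0) return(NA_real_)
  length(intersect(g, s)) / length(g)
}

# Exact likelihood by summing over all internal-state assignments, for
# symmetric k-state models. seqs: integer matrix (taxa x sites), states in
# 1..k, rows named by taxon.
oracle_lnl <- function(tree, seqs, k) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- ntip + tr$Nnode
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), tr$Nnode)))
  ptrans <- function(t, same) {
    e <- exp(-k * t / (k - 1))
    ifelse(same, 1 / k + (k - 1) / k * e, (1 - e) / k)
  }
  nsite <- ncol(seqs)
  lnl <- 0
  for (s in seq_len(nsite)) {
    state <- function(node, combo) {
      if (node <= ntip) seqs[tr$tip.label[node], s]
      else combo[node - ntip]
    }
    tot <- 0
    for (r in seq_len(nrow(combos))) {
      combo <- combos[r, ]
      p <- 1 / k
      for (e in seq_len(nrow(tr$edge))) {
        sp <- state(tr$edge[e, 1], combo)
        sc <- state(tr$edge[e, 2], combo)
        p <- p * ptrans(tr$edge.length[e], sp == sc)
      }
      tot <- tot + p
    }
    lnl <- lnl + log(tot)
  }
  as.numeric(lnl)
}

# Turn an integer state matrix into a phyDat alignment.
as_phyDat_states <- function(seqs, type = c("DNA", "AA")) {
  type <- match.arg(type)
  lv <- if (type == "DNA") c("a", "c", "g", "t") else
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
      "P", "S", "T", "W", "Y", "V")
  m <- matrix(lv[seqs], nrow = nrow(seqs), dimnames = dimnames(seqs))
  phangorn::phyDat(m, type = type)
}

# Random ultrametric chronogram with a fixed seed offset.
random_chronogram <- function(n, height = 0.5, seed = NULL) {
  rescale_height(simulate_yule(n, 1, seed = seed), height)
}

# Species tree with an OUT outgroup, as built by the fixture generator.
fixture_species_tree_for_tests <- function(n_ingroup, height, seed) {
  set.seed(seed)
  geneshop:::fixture_species_tree(n_ingroup, height)
}
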