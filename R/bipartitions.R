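# Canonical key for one side of a split: sorted labels joined by "|".
split_key <- function(taxa) paste(sort(taxa), collapse = "|")

# All splits of the unrooted topology of `tree`, as canonical keys of the
# side NOT containing the reference taxon (lexicographically smallest tip).
# With trivial = FALSE only nontrivial splits (both sides >= 2) are kept.
unrooted_splits <- function(tree, trivial = FALSE) {
  tips <- tree$tip.label
  ref <- sort(tips)[1L]
  clades <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in clades) {
    side <- tips[cl]
    if (ref %in% side) side <- setdiff(tips, side)
    n <- length(side)
    if (n == 0L || n == length(tips)) next
    if (!trivial && (n < 2L || n > length(tips) - 2L)) next
    keys <- c(keys, split_key(side))
  }
  if (trivial) # rooted clade enumeration misses tip splits; add them
    keys <- c(keys, vapply(setdiff(tips, ref), split_key, ""))
  unique(keys)
}

#' Extract nontrivial bipartitions from a tree
#'
#' One bipartition per internal edge of the unrooted topology, after
#' restricting the tree to `universe`. Trivial splits (a side with fewer
#' than two taxa) are excluded; a split and its complement are the same
#' object. Trees with fewer than four taxa in `universe` yield an empty set.
#'
#' @param tree a `phylo` object.
#' @param universe taxon set defining the split universe; defaults to the
#'   tree's tips. Tips outside `universe` are pruned first.
#' @return object of class `bipartition_set`: character vector of canonical
#'   split keys (sorted taxa of the side not holding the reference taxon,
#'   joined by `|`), with attributes `universe` and `taxa` (tips used).
#' @examples
#' extract_bipartitions(read_newick("((A:1,B:1):1,(C:1,D:1):1);"))
#' @export
extract_bipartitions <- function(tree, universe = tree$tip.label) {
  stopifnot(inherits(tree, "phylo"))
  extra <- setdiff(tree$tip.label, universe)
  taxa <- setdiff(tree$tip.label, extra)
  if (length(taxa) < 4L) {
    out <- character(0)
  } else {
    if (length(extra)) {
      # keep >= 3 tips guaranteed by the branch above
      tree <- ape::drop.tip(tree, extra, collapse.singles = TRUE)
    }
    out <- unrooted_splits(tree, trivial = FALSE)
  }
  structure(sort(out), class = "bipartition_set",
            universe = sort(universe), taxa = sort(taxa))
}

#' @export
print.bipartition_set <- function(x, ...) {
  cat(length(x), "nontrivial bipartition(s) on",
      length(attr(x, "taxa")), "taxa\n")
  for (s in unclass(x)) cat(" ", s, "\n")
  invisible(x)
}

#' Topological concordance of a gene tree with a species tree
#'
#' Both trees are restricted to their shared taxon set; nontrivial splits of
#' the unrooted topologies are compared. The concordance proportion is the
#' fraction of the gene tree's splits also present in the species tree, so
#' 1.0 indicates complete agreement with the species-tree topology.
#' Bipartitions are unrooted objects, so the result is invariant to the
#' rooting of either tree. With `denominator = "species"` the species tree's
#' split count is used instead.
#'
#' @param gene_tree,species_tree `phylo` objects sharing at least 4 taxa.
#' @param denominator which tree's split count divides the shared count.
#' @return object of class `concordance`: list with `concordance`,
#'   `shared_count`, `gene_biparts`, `species_biparts`, `shared_taxa`.
#'   `concordance` is `NA` when the denominator tree has no nontrivial
#'   splits (fully unresolved).
#' @examples
#' sp <- read_newick("((A:1,B:1):1,((C:1,D:1):1,E:2):1);")
#' concordance_proportion(sp, sp)$concordance  # 1
#' @export
concordance_proportion <- function(gene_tree, species_tree,
                                   denominator = c("gene", "species")) {
  denominator <- match.arg(denominator)
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4L)
    stop("insufficient taxon overlap: ", length(shared), " shared taxa (< 4)")
  g <- extract_bipartitions(gene_tree, universe = shared)
  s <- extract_bipartitions(species_tree, universe = shared)
  shared_count <- length(intersect(unclass(g), unclass(s)))
  denom <- if (denominator == "gene") length(g) else length(s)
  out <- list(
    concordance = if (denom > 0L) shared_count / denom else NA_real_,
    shared_count = shared_count,
    gene_biparts = length(g),
    species_biparts = length(s),
    shared_taxa = sort(shared))
  class(out) <- "concordance"
  out
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance %.4g (%d/%d splits shared; %d shared taxa)\n",
              x$concordance, x$shared_count, x$gene_biparts,
              length(x$shared_taxa)))
  invisible(x)
}
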