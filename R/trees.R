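#' Read and validate a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates the result: a
#' single tree, unique non-empty tip labels, non-negative branch lengths
#' (missing lengths default to 0). Square-bracket comments are ignored and
#' quoted labels are supported by the underlying parser.
#'
#' @param text Newick string (one tree terminated by `;`).
#' @param file path to a Newick file; exactly one of `text`/`file`.
#' @return a rooted tree of class `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("provide exactly one of `text` or `file`")
  src <- if (is.null(file)) "string" else file
  tr <- tryCatch(
    if (is.null(file)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) stop("Newick parse error in ", src, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error in ", src, ": ",
                               conditionMessage(w), call. = FALSE))
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("expected a single tree in ", src, ", found ", length(tr))
    tr <- tr[[1L]]
  }
  if (!inherits(tr, "phylo") || is.null(tr$tip.label) || tr$Nnode < 1L ||
      any(!nzchar(tr$tip.label)))
    stop("Newick parse error in ", src, ": no valid tree found")
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stop("empty tip labels")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  if (anyNA(tree$edge.length)) tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed")
  tree
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 15L) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Root a tree on the edge separating an outgroup
#'
#' Reroots on the edge that separates `outgroup` from the remaining taxa.
#' The outgroup must be present and must form one side of a single edge of
#' the unrooted topology. Total tree length and the unrooted bipartition set
#' are preserved.
#'
#' @param tree a `phylo` object (rooted or not).
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted `phylo` with the ingroup as one child of the root.
#' @examples
#' tr <- read_newick("(A:1,B:1,(C:1,D:1):1);")
#' rooted <- root_by_outgroup(tr, "D")
#' @export
root_by_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"), length(outgroup) >= 1L)
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(setdiff(tree$tip.label, outgroup)) < 2L)
    stop("fewer than 2 ingroup taxa remain")
  utr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  if (!outgroup_separable(utr, outgroup))
    stop("outgroup {", paste(sort(outgroup), collapse = ", "),
         "} is not separable from the ingroup by a single edge")
  ape::root(utr, outgroup = outgroup, resolve.root = TRUE)
}

# TRUE when `taxa` forms one side of an edge of the unrooted topology.
outgroup_separable <- function(utree, taxa) {
  if (length(taxa) == 1L) return(TRUE)
  key <- split_key(sort(taxa))
  splits <- unrooted_splits(utree, trivial = TRUE)
  key %in% splits
}

#' Drop taxa from a rooted tree, preserving root-to-tip paths
#'
#' Removes the given tips; internal nodes left with a single child are
#' suppressed and their branch lengths summed. If the root itself is left
#' with one child, the stem is retained as `$root.edge` so that the
#' root-to-tip path lengths of surviving taxa are unchanged (and reported by
#' [tree_stats()]).
#'
#' @param tree rooted `phylo`.
#' @param drop character vector of tip labels to remove.
#' @param min_tips smallest allowed number of surviving tips.
#' @return the pruned `phylo`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' pr <- prune_taxa(tr, "C")
#' tree_stats(pr)$root_to_tip  # A and B still at depth 2
#' @export
prune_taxa <- function(tree, drop, min_tips = 3L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(drop) == 0L) return(tree)
  missing <- setdiff(drop, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  keep <- setdiff(tree$tip.label, drop)
  if (length(keep) < min_tips)
    stop("pruning would leave ", length(keep), " tips (< ", min_tips, ")")
  ape::drop.tip(tree, drop, collapse.singles = TRUE, root.edge = 1L)
}

#' Per-tree winnowing statistics
#'
#' Computes, on a rooted phylogram, the statistics the gene-shopping
#' procedure consumes: total tree length (a proxy for discernible
#' information content), root-to-tip path lengths per tip, their variance (a
#' proxy for clock-likeness: 0 on an ultrametric tree), and per-tip
#' deviations from the mean root-to-tip path. The variance uses the sample
#' (n-1) estimator. A retained root stem (`$root.edge`) counts towards the
#' paths and the tree length.
#'
#' @param tree rooted `phylo` with at least 2 tips.
#' @return object of class `tree_stats`: list with `tree_length`,
#'   `root_to_tip` (named numeric), `rtt_variance`, `rtt_deviations`.
#' @examples
#' ts <- tree_stats(read_newick("((A:1,B:2):1,C:2);"))
#' ts$rtt_variance  # 1/3
#' @export
tree_stats <- function(tree) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2L)
  tree <- validate_tree(tree)
  stem <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))] + stem
  names(depth) <- tree$tip.label
  out <- list(
    tree_length = sum(tree$edge.length) + stem,
    root_to_tip = depth,
    rtt_variance = stats::var(depth),
    rtt_deviations = depth - mean(depth))
  class(out) <- "tree_stats"
  out
}

#' @export
print.tree_stats <- function(x, ...) {
  cat(sprintf("tree_length %.6g  rtt_variance %.6g  (%d tips)\n",
              x$tree_length, x$rtt_variance, length(x$root_to_tip)))
  invisible(x)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths equal within a relative tolerance
#' (absolute when the tree height is ~0).
#'
#' @param tree rooted `phylo`.
#' @param tol relative tolerance.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-9) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  h <- max(d)
  if (h <= tol) return(TRUE)
  (h - min(d)) / h <= tol
}

#' Height of a rooted tree
#'
#' Maximum root-to-tip path length (excluding any root stem).
#' @param tree rooted `phylo`.
#' @return numeric.
#' @export
tree_height <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}
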