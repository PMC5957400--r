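#' Per-gene winnowing statistics
#'
#' For every rooted gene tree: (i) root by the outgroup (when given), (ii)
#' score bipartition concordance with the species tree on the full rooted
#' tree, (iii) prune the outgroup, and (iv) compute root-to-tip variance and
#' tree length on the ingroup. Outgroups enter the concordance comparison
#' but are excluded from the clock statistics. Genes that cannot be rooted
#' or end up with too few taxa are skipped with a warning and recorded in
#' the `skipped` attribute.
#'
#' @param gene_trees named list of `phylo` objects (names are gene ids); an
#'   unnamed list gets ids `gene1..geneN`.
#' @param species_tree `phylo`, the focal species-tree topology.
#' @param outgroup character vector of outgroup taxa (may be empty when the
#'   gene trees are already rooted). Outgroup taxa present in a gene tree
#'   are used for rooting; genes missing the whole outgroup are skipped.
#' @return a `data.frame` with one row per gene, sorted by gene id:
#'   `gene`, `concordance`, `rtt_variance`, `tree_length`, `n_tips`
#'   (ingroup tips used), `missing_taxa` (flag: ingroup taxa absent
#'   relative to the species tree). Attribute `skipped` is a data.frame of
#'   skipped genes and reasons.
#' @export
compute_gene_stats <- function(gene_trees, species_tree,
                               outgroup = character(0)) {
  stopifnot(is.list(gene_trees), inherits(species_tree, "phylo"))
  if (length(gene_trees) && is.null(names(gene_trees)))
    names(gene_trees) <- paste0("gene", seq_along(gene_trees))
  ingroup_sp <- setdiff(species_tree$tip.label, outgroup)
  rows <- list()
  skipped <- list()
  for (id in sort(names(gene_trees))) {
    res <- tryCatch({
      tr <- validate_tree(gene_trees[[id]])
      og <- intersect(outgroup, tr$tip.label)
      if (length(outgroup) && length(og) == 0L)
        stop("no outgroup taxon present")
      if (length(og)) tr <- root_by_outgroup(tr, og)
      if (!ape::is.rooted(tr)) stop("gene tree is unrooted")
      conc <- concordance_proportion(tr, species_tree)$concordance
      ing <- if (length(og)) prune_taxa(tr, og) else tr
      st <- tree_stats(ing)
      data.frame(gene = id, concordance = conc,
                 rtt_variance = st$rtt_variance,
                 tree_length = st$tree_length,
                 n_tips = length(st$root_to_tip),
                 missing_taxa = length(setdiff(ingroup_sp,
                                               names(st$root_to_tip))) > 0L,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      warning("skipping gene ", id, ": ", res, call. = FALSE)
      skipped[[id]] <- res
    } else rows[[id]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), concordance = numeric(0),
               rtt_variance = numeric(0), tree_length = numeric(0),
               n_tips = integer(0), missing_taxa = logical(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(gene = names(skipped),
                                     reason = unlist(unname(skipped)),
                                     stringsAsFactors = FALSE)
  out
}

#' Ranking policy for gene shopping
#'
#' The default mirrors the winnowing sort order: species-tree concordance
#' (descending) first, then root-to-tip variance (ascending: most
#' clock-like first), then tree length (descending: most informative
#' first). `thresholds` are optional hard filters applied before sorting
#' (`concordance` and `tree_length` are minima, `rtt_variance` a maximum).
#'
#' @param order permutation of
#'   `c("concordance", "rtt_variance", "tree_length")`.
#' @param thresholds named list/vector, subset of the three criteria.
#' @param n_select default number of genes [select_genes] keeps.
#' @return object of class `ranking_policy`.
#' @export
ranking_policy <- function(order = c("concordance", "rtt_variance",
                                     "tree_length"),
                           thresholds = NULL, n_select = 3L) {
  crit <- c("concordance", "rtt_variance", "tree_length")
  if (!identical(sort(order), sort(crit)))
    stop("`order` must be a permutation of: ", paste(crit, collapse = ", "))
  if (!is.null(thresholds)) {
    thresholds <- as.list(thresholds)
    bad <- setdiff(names(thresholds), crit)
    if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(n_select >= 1)
  structure(list(order = order, thresholds = thresholds,
                 n_select = as.integer(n_select)),
            class = "ranking_policy")
}

#' Rank genes by the winnowing criteria
#'
#' Lexicographic sort of a gene-statistics table by the policy's criterion
#' order and directions, after applying any hard thresholds. The sort is
#' stable (tied records keep their input order), so tables emitted by
#' [compute_gene_stats()], which are gene-id-sorted, get a bit-reproducible
#' gene-id tie-break.
#'
#' @param records data.frame from [compute_gene_stats()] (columns `gene`,
#'   `concordance`, `rtt_variance`, `tree_length`).
#' @param policy a [ranking_policy].
#' @return the reordered (and possibly thresholded) data.frame.
#' @examples
#' recs <- data.frame(gene = c("g1", "g2", "g3"),
#'                    concordance = c(1, 0.8, 1),
#'                    rtt_variance = c(0.01, 0.001, 0.002),
#'                    tree_length = c(2, 5, 1))
#' rank_genes(recs)$gene  # g3, g1, g2
#' @export
rank_genes <- function(records, policy = ranking_policy()) {
  stopifnot(is.data.frame(records), inherits(policy, "ranking_policy"),
            all(c("gene", policy$order) %in% names(records)))
  if (nrow(records) == 0L) stop("empty gene table")
  th <- policy$thresholds
  keep <- rep(TRUE, nrow(records))
  if (!is.null(th)) {
    if (!is.null(th$concordance)) keep <- keep &
        !is.na(records$concordance) & records$concordance >= th$concordance
    if (!is.null(th$rtt_variance)) keep <- keep &
        records$rtt_variance <= th$rtt_variance
    if (!is.null(th$tree_length)) keep <- keep &
        records$tree_length >= th$tree_length
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all records excluded by thresholds")
    return(out)
  }
  sign_of <- c(concordance = -1, rtt_variance = 1, tree_length = -1)
  keys <- lapply(policy$order, function(cr) sign_of[[cr]] * out[[cr]])
  ord <- do.call(order, c(keys, list(method = "radix"))) # radix is stable
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-ranked genes
#'
#' Keeps the first `n` rows of a ranked table and, when per-gene alignment
#' lengths are supplied, builds a concatenation manifest whose per-gene
#' partitions tile the concatenated alignment exactly.
#'
#' @param ranked data.frame from [rank_genes()].
#' @param n number of genes to keep; if fewer are available all are
#'   returned with a warning.
#' @param alignment_lengths optional named vector of per-gene alignment
#'   lengths (sites), named by gene id.
#' @return the selected rows; when lengths are given, attribute `manifest`
#'   is a data.frame `gene`, `length`, `start`, `end` (1-based, inclusive).
#' @export
select_genes <- function(ranked, n = 3L, alignment_lengths = NULL) {
  stopifnot(is.data.frame(ranked), n >= 1)
  if (n > nrow(ranked)) {
    warning("requested ", n, " genes but only ", nrow(ranked),
            " available; returning all")
    n <- nrow(ranked)
  }
  out <- ranked[seq_len(n), , drop = FALSE]
  if (!is.null(alignment_lengths)) {
    miss <- setdiff(out$gene, names(alignment_lengths))
    if (length(miss))
      stop("no alignment length for gene(s): ", paste(miss, collapse = ", "))
    len <- as.integer(alignment_lengths[out$gene])
    end <- cumsum(len)
    attr(out, "manifest") <- data.frame(
      gene = out$gene, length = len,
      start = c(1L, head(end, -1L) + 1L), end = end,
      stringsAsFactors = FALSE)
  }
  out
}

#' Merge per-gene statistic tables
#'
#' Joins tables produced by separate pipeline stages (e.g. the CLI's
#' `stats`, `bp` and `clocktest` outputs) on the `gene` column, keeping
#' genes present in all tables.
#'
#' @param ... data.frames, each with a `gene` column.
#' @return the merged data.frame, sorted by gene id.
#' @export
combine_gene_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L,
            all(vapply(tabs, function(x) "gene" %in% names(x), TRUE)))
  out <- Reduce(function(a, b) merge(a, b, by = "gene"), tabs)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
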