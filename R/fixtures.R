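fixture_profiles <- function() {
  list(
    clock      = list(kind = "strict", rate = 1, n_genes = 5L),
    noisy25    = list(kind = "noisy_clock", rate = 1, noise_sd = 0.25,
                      n_genes = 5L),
    noisy75    = list(kind = "noisy_clock", rate = 1, noise_sd = 0.75,
                      n_genes = 5L),
    ucln05     = list(kind = "ucln", mean_log = -0.5, stdev_log = 0.5,
                      n_genes = 5L),
    ucln10     = list(kind = "ucln", mean_log = -0.5, stdev_log = 1.0,
                      n_genes = 5L),
    mixed_pool = list(kind = "mixed", n_genes = 12L))
}

# Ultrametric species tree: Yule ingroup plus one outgroup tip diverging
# at 1.2x the ingroup height, rescaled to `height`.
fixture_species_tree <- function(n_ingroup, height) {
  ing <- simulate_yule(n_ingroup, 1)
  ing$tip.label <- paste0("t", seq_len(n_ingroup))
  h <- tree_height(ing)
  og_h <- 1.2 * h
  txt <- sprintf("(%s:%.17g,OUT:%.17g);",
                 sub(";$", "", write_newick(ing)), og_h - h, og_h)
  rescale_height(read_newick(txt), height)
}

#' Generate a deterministic fixture directory
#'
#' Packages the simulation scenarios as reusable on-disk fixtures: a rooted
#' ultrametric species tree with an `OUT` outgroup tip, per-gene phylograms
#' (true chronogram decorated with branch rates), gap-free alignments, a
#' truth table, and the expected winnowing table computed from the true
#' gene trees. Everything is a deterministic function of `(profile, seed)`.
#'
#' Profiles: `clock` (strict, rate 1), `noisy25`/`noisy75` (noisy clock,
#' rate 1, noise 0.25/0.75), `ucln05`/`ucln10` (UCLN, mean.log -0.5,
#' stdev.log 0.5/1.0), and `mixed_pool` (one third each clock / noisy
#' clock 0.75 / UCLN 1.0).
#'
#' @param profile one of the profile names above.
#' @param dir output directory (created; must not already contain files).
#' @param seed integer seed (mandatory: fixtures are reproducible).
#' @param n_taxa ingroup taxa in the species tree.
#' @param height species-tree root height (time units).
#' @param length alignment length in sites.
#' @param model a [subst_model].
#' @return (invisibly) the manifest list, also written as `manifest.json`.
#' @export
make_fixtures <- function(profile, dir, seed, n_taxa = 12L, height = 0.5,
                          length = 1500L, model = jc_model()) {
  profiles <- fixture_profiles()
  if (!profile %in% names(profiles))
    stop("unknown profile '", profile, "'; valid profiles: ",
         paste(names(profiles), collapse = ", "))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  p <- profiles[[profile]]
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  with_seed(as.integer(seed), {
    sp <- fixture_species_tree(n_taxa, height)
    write_newick(sp, file.path(dir, "species.tre"))
    n <- p$n_genes
    kinds <- if (p$kind == "mixed")
      rep(c("strict", "noisy_clock", "ucln"), length.out = n)
    else rep(p$kind, n)
    truth <- vector("list", n)
    gene_trees <- list()
    for (j in seq_len(n)) {
      id <- sprintf("gene%03d", j)
      dec <- switch(kinds[j],
        strict = rate_decoration("strict", rate = p$rate %||% 1),
        noisy_clock = rate_decoration("noisy_clock", rate = p$rate %||% 1,
                                      noise_sd = p$noise_sd %||% 0.75),
        ucln = rate_decoration("ucln", mean_log = p$mean_log %||% -0.5,
                               stdev_log = p$stdev_log %||% 1.0))
      phy <- apply_rates(sp, dec)
      aln <- simulate_alignment(phy, model, length)
      write_newick(phy, file.path(dir, "genes", paste0(id, ".tre")))
      write_fasta_alignment(aln, file.path(dir, "alignments",
                                           paste0(id, ".fasta")))
      gene_trees[[id]] <- phy
      st <- tree_stats(prune_taxa(phy, "OUT"))
      truth[[j]] <- data.frame(
        gene = id, kind = kinds[j],
        rate = if (kinds[j] == "ucln") NA_real_ else p$rate %||% 1,
        noise_sd = if (kinds[j] == "noisy_clock") p$noise_sd %||% 0.75 else
          if (kinds[j] == "strict") 0 else NA_real_,
        stdev_log = if (kinds[j] == "ucln") p$stdev_log %||% 1.0 else
          NA_real_,
        true_height = height, tree_length = st$tree_length,
        rtt_variance = st$rtt_variance)
    }
    write_tsv(do.call(rbind, truth), file.path(dir, "truth.tsv"))
    tab <- compute_gene_stats(gene_trees, sp, outgroup = "OUT")
    write_tsv(tab, file.path(dir, "stats.tsv"))
    write_tsv(rank_genes(tab), file.path(dir, "expected_shop.tsv"))
    manifest <- run_manifest("fixtures",
                             list(profile = profile, seed = seed,
                                  n_taxa = n_taxa, height = height,
                                  length = length, model = model$name),
                             outputs = c("species.tre", "truth.tsv",
                                         "stats.tsv", "expected_shop.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  if (!file.exists(file)) stop("input table not found: ", file)
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

run_manifest <- function(command, params, outputs = character(0)) {
  list(command = command, params = params, outputs = outputs,
       version = as.character(utils::packageVersion("geneshop")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
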