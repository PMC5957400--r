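# Alignments are phangorn `phyDat` objects throughout: taxon-indexed,
# pattern-compressed character matrices whose contrast matrix treats gaps
# and ambiguity codes as partial likelihoods of ones (missing data).

#' Read a FASTA alignment
#'
#' @param file path to an uncompressed FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return a [phangorn::phyDat] alignment.
#' @export
read_fasta_alignment <- function(file, type = c("DNA", "AA")) {
  type <- match.arg(type)
  aln <- phangorn::read.phyDat(file, format = "fasta", type = type)
  if (anyDuplicated(names(aln)))
    stop("duplicate taxon names in ", file)
  aln
}

#' Write a FASTA alignment
#'
#' @param aln a [phangorn::phyDat] alignment.
#' @param file output path.
#' @export
write_fasta_alignment <- function(aln, file) {
  stopifnot(inherits(aln, "phyDat"))
  phangorn::write.phyDat(aln, file, format = "fasta")
  invisible(file)
}

#' Number of columns of an alignment
#' @param aln a [phangorn::phyDat] alignment.
#' @return integer number of sites.
#' @export
alignment_length <- function(aln) {
  stopifnot(inherits(aln, "phyDat"))
  length(attr(aln, "index"))
}

# Infer the engine's model from a phyDat alphabet unless given.
default_model <- function(aln, model = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "subst_model"))
    if (model$k != attr(aln, "nc"))
      stop("model has ", model$k, " states but alignment has ",
           attr(aln, "nc"))
    return(model)
  }
  nc <- attr(aln, "nc")
  if (nc == 4L) jc_model()
  else if (nc == 20L) poisson_model()
  else stop("no default symmetric model for ", nc, "-state data")
}
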