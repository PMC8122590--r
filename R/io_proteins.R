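#' Read a proteome FASTA into a protein record table
#'
#' Reads amino-acid sequences and derives a gene identifier per protein,
#' either from a `gene=<id>` token in the FASTA description or, failing
#' that, by stripping a trailing isoform suffix (`.p1`, `.t2`, `-RA`, ...)
#' from the sequence name.
#'
#' @param path FASTA file of protein sequences.
#' @return Data frame with columns `protein_id`, `gene_id` and
#'   `sequence_length`.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  header <- names(seqs)
  protein_id <- sub("\\s.*$", "", header)
  gene_id <- ifelse(
    grepl("gene=([^ ]+)", header),
    sub(".*gene=([^ ]+).*", "\\1", header),
    sub("([.-](p|t|R)?[A-Z0-9]+)$", "", protein_id)
  )
  if (anyDuplicated(protein_id)) {
    stop("duplicate protein_id in FASTA: ",
         protein_id[duplicated(protein_id)][1L])
  }
  data.frame(protein_id = protein_id, gene_id = gene_id,
             sequence_length = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}

#' Select one protein per gene (longest isoform)
#'
#' Collapses a proteome to a single representative protein per gene: the
#' isoform with the greatest sequence length, ties broken by the
#' lexicographically smallest `protein_id`. This replaces redundancy
#' removal by clustering tools with a deterministic per-gene policy, so
#' that every TF is counted once per gene.
#'
#' @param proteins data frame with columns `protein_id`, `gene_id`,
#'   `sequence_length` (see [read_protein_fasta()]).
#' @return The subset of `proteins` with exactly one row per `gene_id`,
#'   ordered by `gene_id`.
#' @export
select_longest_isoform <- function(proteins) {
  if (nrow(proteins) == 0L) return(proteins)
  if (any(proteins$sequence_length < 1L)) {
    stop("sequence_length must be >= 1")
  }
  ord <- order(proteins$gene_id, -proteins$sequence_length,
               proteins$protein_id)
  sorted <- proteins[ord, , drop = FALSE]
  keep <- !duplicated(sorted$gene_id)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
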