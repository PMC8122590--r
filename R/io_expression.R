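#' Read a gene-by-stage FPKM table
#'
#' Reads a TSV with one row per gene (first column: gene identifier) and
#' one column per developmental stage. Columns may also be per-replicate
#' measurements named `<stage>_<replicate>` (e.g. `tb_1`, `tb_2`, `tb_3`);
#' replicates of a stage are collapsed by their mean. Columns are returned
#' in the order given by `stage_order` regardless of file order.
#'
#' @param path TSV file. First column gene ids, remaining columns FPKM.
#' @param stage_order character vector of stage names expected in the
#'   header (directly or as replicate groups); defaults to [dev_stages()].
#' @return Numeric matrix, genes x stages, with `rownames` the gene ids
#'   and `colnames` equal to `stage_order`.
#' @export
read_expression_table <- function(path, stage_order = dev_stages()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column plus stages")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in expression table: ",
         gene_ids[duplicated(gene_ids)][1L])
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) stop("expression table contains missing values")
  if (any(vals < 0)) stop("FPKM values must be non-negative")
  rownames(vals) <- gene_ids

  # map each column to its stage: exact name, or "<stage>_<suffix>"
  col_stage <- rep(NA_character_, ncol(vals))
  for (s in stage_order) {
    hit <- colnames(vals) == s | startsWith(colnames(vals), paste0(s, "_"))
    col_stage[hit] <- s
  }
  missing <- setdiff(stage_order, col_stage)
  if (length(missing) > 0L) {
    stop("stage(s) missing from expression table header: ",
         paste(missing, collapse = ", "))
  }
  out <- vapply(stage_order, function(s) {
    rowMeans(vals[, col_stage == s, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(gene_ids, stage_order))
  out
}

#' Write a gene-by-stage FPKM table
#'
#' Inverse of [read_expression_table()] for stage-level matrices; values
#' are written at full precision so that a write-read round trip is
#' bitwise exact.
#'
#' @param mat numeric matrix, genes x stages, with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene loci from a BED file
#'
#' Imports a BED file of gene loci and returns them with the BED
#' convention kept internally: 0-based, half-open intervals.
#'
#' @param path BED file (at least 4 columns: chrom, start, end, name).
#' @return Data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end` (0-based half-open) and `strand` (`+`, `-` or `.`).
#' @export
read_bed_loci <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0("locus", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- data.frame(
    gene_id = nm,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # back to BED 0-based
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  if (any(out$start < 0L) || any(out$end <= out$start)) {
    stop("invalid BED interval: need 0 <= start < end")
  }
  out
}
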