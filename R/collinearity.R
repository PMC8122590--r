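## Hox/Fox positional analysis: chromosomal distribution, expression
## onset calling, and subcluster temporal collinearity (STC): contiguous
## runs of cluster genes whose expression-onset order matches (tau = +1)
## or exactly reverses (tau = -1) their genomic order.

#' Chromosomal distribution of gene loci
#'
#' @param loci data frame of gene loci (see [read_bed_loci()]).
#' @return List with `counts` (named integer vector, genes per
#'   chromosome) and `single_chromosome` (`TRUE` when all loci share one
#'   chromosome).
#' @export
chromosome_census <- function(loci) {
  tab <- table(loci$chromosome)
  counts <- setNames(as.integer(tab), names(tab))
  list(counts = counts,
       single_chromosome = length(counts) == 1L && nrow(loci) > 0L)
}

#' Expression onset stage of a gene
#'
#' The earliest stage (canonical order) at which the gene's FPKM is
#' strictly above `threshold` (default 10, the expressed-gene cutoff).
#'
#' @param matrix genes x stages FPKM matrix, stage columns in canonical
#'   order.
#' @param gene_id gene to look up.
#' @param threshold FPKM cutoff.
#' @return Stage name, or `NA_character_` when the gene never exceeds
#'   the threshold.
#' @export
onset_stage <- function(matrix, gene_id, threshold = 10) {
  if (!gene_id %in% rownames(matrix)) stop("unknown gene: ", gene_id)
  above <- which(matrix[gene_id, ] > threshold)
  if (length(above) == 0L) return(NA_character_)
  colnames(matrix)[above[1L]]
}

#' Onset stages for every gene of a matrix
#'
#' @inheritParams onset_stage
#' @return Named character vector (`NA` where never above threshold).
#' @export
onset_stages <- function(matrix, threshold = 10) {
  setNames(vapply(rownames(matrix), function(g)
    onset_stage(matrix, g, threshold), character(1L)), rownames(matrix))
}

#' Kendall rank correlation between genomic order and onset order
#'
#' Kendall's tau-b (tie-corrected) between the genomic rank of a run of
#' cluster genes and the rank of their expression-onset stages. Onset
#' stages are heavily tied ordinal data, hence tau-b rather than
#' Spearman. When either ranking is constant tau-b is undefined and 0 is
#' returned.
#'
#' @param genomic_rank numeric vector of genomic positions/ranks
#'   (length >= 3).
#' @param onset_rank numeric vector of onset-stage ranks, same length,
#'   no missing values (filter genes without onsets first).
#' @return tau in `[-1, 1]`.
#' @export
collinearity_tau <- function(genomic_rank, onset_rank) {
  if (length(genomic_rank) != length(onset_rank)) {
    stop("rank vectors must have equal length")
  }
  if (length(genomic_rank) < 3L) stop("need at least 3 genes")
  if (anyNA(genomic_rank) || anyNA(onset_rank)) {
    stop("missing onset rank; filter genes without onsets first")
  }
  tau <- suppressWarnings(cor(genomic_rank, onset_rank,
                              method = "kendall"))
  if (is.na(tau)) 0 else tau
}

stage_rank <- function(stage, stage_order = dev_stages()) {
  r <- match(stage, stage_order)
  if (any(is.na(r) & !is.na(stage))) {
    stop("unknown stage(s): ",
         paste(stage[is.na(r) & !is.na(stage)], collapse = ", "))
  }
  r
}

#' Find temporally collinear subclusters
#'
#' Scans a genomically ordered gene cluster for all maximal contiguous
#' windows (length >= `min_len`) whose members all have expression
#' onsets and whose genomic-vs-onset Kendall tau is exactly +1 (forward)
#' or -1 (reverse). Genes without an onset break windows. A window is
#' maximal when no one-gene extension also qualifies.
#'
#' @param cluster data frame in genomic order with columns `gene_id` and
#'   `onset` (stage name or `NA`).
#' @param min_len minimum window length (default 3).
#' @param perfect_only currently only perfect collinearity (|tau| = 1)
#'   is reported; `FALSE` is reserved.
#' @param stage_order canonical stage order used to rank onsets.
#' @return Data frame with one row per maximal window: `start`, `end`
#'   (indices into `cluster`), `genes` (list column), `tau` and
#'   `orientation` (`"forward"`/`"reverse"`).
#' @export
find_collinear_subclusters <- function(cluster, min_len = 3L,
                                       perfect_only = TRUE,
                                       stage_order = dev_stages()) {
  stopifnot(all(c("gene_id", "onset") %in% names(cluster)))
  if (!perfect_only) stop("perfect_only = FALSE is not implemented")
  n <- nrow(cluster)
  onset_r <- stage_rank(cluster$onset, stage_order)
  qualifies <- function(s, e) {
    idx <- s:e
    if (anyNA(onset_r[idx])) return(NA_real_)
    collinearity_tau(idx, onset_r[idx])
  }
  res <- list()
  if (n >= min_len) {
    for (s in 1:(n - min_len + 1L)) {
      for (e in (s + min_len - 1L):n) {
        tau <- qualifies(s, e)
        if (is.na(tau) || abs(abs(tau) - 1) > 1e-12) next
        # maximality: neither extension qualifies
        left <- if (s > 1L) qualifies(s - 1L, e) else NA_real_
        right <- if (e < n) qualifies(s, e + 1L) else NA_real_
        ext_ok <- function(t) !is.na(t) && abs(abs(t) - 1) <= 1e-12
        if (ext_ok(left) || ext_ok(right)) next
        res[[length(res) + 1L]] <- data.frame(
          start = s, end = e, tau = tau,
          orientation = if (tau > 0) "forward" else "reverse",
          stringsAsFactors = FALSE)
        res[[length(res)]]$genes <- I(list(cluster$gene_id[s:e]))
      }
    }
  }
  if (length(res) == 0L) {
    out <- data.frame(start = integer(), end = integer(), tau = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
    out$genes <- I(list())
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Compare Hox-cluster arrangements between two species
#'
#' @param cluster_a,cluster_b data frames in genomic order with columns
#'   `pg` (paralog group, integer 1-13) and optionally `chromosome`.
#' @return List with `shared_pgs` (sorted integer vector), `same_order`
#'   (`TRUE` when the shared paralog groups appear in the same relative
#'   order, or its exact reversal, in both clusters) and `same_linkage`
#'   (`TRUE` when both clusters each lie on a single chromosome;
#'   `NA` when chromosomes are not given).
#' @export
compare_arrangements <- function(cluster_a, cluster_b) {
  stopifnot("pg" %in% names(cluster_a), "pg" %in% names(cluster_b))
  shared <- sort(intersect(cluster_a$pg, cluster_b$pg))
  if (length(shared) == 0L) {
    same_order <- TRUE
  } else {
    a <- cluster_a$pg[cluster_a$pg %in% shared]
    b <- cluster_b$pg[cluster_b$pg %in% shared]
    same_order <- identical(a, b) || identical(a, rev(b))
  }
  same_linkage <- if (is.null(cluster_a$chromosome) ||
                      is.null(cluster_b$chromosome)) {
    NA
  } else {
    length(unique(cluster_a$chromosome)) == 1L &&
      length(unique(cluster_b$chromosome)) == 1L
  }
  list(shared_pgs = shared, same_order = same_order,
       same_linkage = same_linkage)
}
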