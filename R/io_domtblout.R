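## hmmscan per-domain table ("domtblout") reader/writer.
##
## One line per domain hit. In hmmscan output the *target* is the Pfam
## profile and the *query* is the protein, so the protein identifier is
## column 4 and the Pfam accession column 2. The first 22 columns are
## whitespace-delimited; the free-text description occupies the remainder.

DOMTBL_MIN_FIELDS <- 22L

#' Read an hmmscan per-domain table
#'
#' Parses the HMMER 3 per-domain tabular output (`--domtblout`) of
#' `hmmscan`, returning one row per domain hit. Pfam accession version
#' suffixes are stripped (`"PF00096.23"` becomes `"PF00096"`) so that
#' joins against a family rules table are robust to Pfam release drift.
#' Envelope coordinates are kept 1-based inclusive on the protein, as
#' printed by HMMER.
#'
#' @param path path to a domtblout file. Lines starting with `#` are
#'   skipped.
#' @return A data frame with columns `protein_id`, `pfam_accession`,
#'   `domain_name`, `full_seq_evalue`, `ind_domain_evalue`, `bit_score`
#'   (full-sequence score), `env_start` and `env_end`, in input order.
#' @export
#' @seealso [write_domtblout()], [simulate_domtblout()]
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("cannot read domtblout file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_domain_hits())
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < DOMTBL_MIN_FIELDS)
  if (length(bad) > 0L) {
    stop("malformed domtblout line ", idx[bad[1L]], ": expected at least ",
         DOMTBL_MIN_FIELDS, " fields, found ", nf[bad[1L]])
  }
  get <- function(i) vapply(fields, `[[`, character(1L), i)
  hits <- data.frame(
    protein_id       = get(4L),
    pfam_accession   = sub("\\.\\d+$", "", get(2L)),
    domain_name      = get(1L),
    full_seq_evalue  = as.numeric(get(7L)),
    ind_domain_evalue = as.numeric(get(13L)),
    bit_score        = as.numeric(get(8L)),
    env_start        = as.integer(get(20L)),
    env_end          = as.integer(get(21L)),
    stringsAsFactors = FALSE
  )
  validate_domain_hits(hits)
  hits
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(), pfam_accession = character(),
             domain_name = character(), full_seq_evalue = numeric(),
             ind_domain_evalue = numeric(), bit_score = numeric(),
             env_start = integer(), env_end = integer(),
             stringsAsFactors = FALSE)
}

validate_domain_hits <- function(hits) {
  req <- c("protein_id", "pfam_accession", "domain_name", "full_seq_evalue",
           "ind_domain_evalue", "bit_score", "env_start", "env_end")
  miss <- setdiff(req, names(hits))
  if (length(miss) > 0L) {
    stop("domain hit table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(hits$full_seq_evalue < 0) || any(hits$ind_domain_evalue < 0)) {
    stop("domain hit e-values must be non-negative")
  }
  if (nrow(hits) > 0L &&
      (any(hits$env_start < 1L) || any(hits$env_end < hits$env_start))) {
    stop("domain hit envelope coordinates must satisfy 1 <= start <= end")
  }
  invisible(hits)
}

#' Write a domain hit table in domtblout layout
#'
#' Serialises a domain hit table back to the hmmscan per-domain tabular
#' dialect, so simulated annotations round-trip through the same reader
#' as real ones. Columns that the internal representation does not carry
#' (alignment coordinates, bias terms) are emitted as placeholders.
#'
#' @param hits data frame as returned by [read_domtblout()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  validate_domain_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"
  ), con)
  if (nrow(hits) > 0L) {
    len <- hits$env_end - hits$env_start + 1L
    # full precision so that write -> read round-trips exactly
    lines <- sprintf(
      "%-20s %-11s %4d %-20s %-11s %4d %s %s %5.1f %3d %3d %s %s %s %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      hits$domain_name, paste0(hits$pfam_accession, ".1"), len,
      hits$protein_id, "-", hits$env_end + 10L,
      sprintf("%.17g", hits$full_seq_evalue),
      sprintf("%.17g", hits$bit_score), 0, 1L, 1L,
      sprintf("%.17g", hits$ind_domain_evalue),
      sprintf("%.17g", hits$ind_domain_evalue),
      sprintf("%.17g", hits$bit_score), 0,
      1L, len, hits$env_start, hits$env_end, hits$env_start, hits$env_end,
      0.95)
    writeLines(lines, con)
  }
  writeLines("#", con)
  invisible(path)
}
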