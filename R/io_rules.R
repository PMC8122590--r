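## Family rule sets: the mapping from Pfam DNA-binding-domain accessions
## to TF families, per-family e-value thresholds, and compound-domain
## subtype rules.

#' Read a TF family rules table
#'
#' The rules table maps Pfam accessions to TF families and optional
#' superfamilies, with an optional per-family e-value threshold override
#' (column `evalue_threshold`; `NA` means the default applies). An
#' optional `is_dbd` column (0/1) marks accessory, non-DNA-binding
#' domains (such as BTB) that participate in compound-domain rules but
#' cannot by themselves make a gene a TF.
#'
#' @param path TSV with columns `pfam_accession`, `family`, optionally
#'   `superfamily`, `evalue_threshold`, `domain_name`, `is_dbd`.
#' @param default_threshold e-value cutoff used for families without an
#'   override (default `1e-4`).
#' @param compound_rules data frame defining compound-domain subtypes
#'   with columns `subtype`, `required` (list of family-name vectors) and
#'   `host_family`. The default defines ZBTB: a gene with passing BTB and
#'   zf-C2H2 domains is a zf-C2H2 family member of subtype ZBTB.
#' @return An object of class `family_rules`.
#' @export
#' @seealso [default_family_rules()]
read_family_rules <- function(path, default_threshold = 1e-4,
                              compound_rules = zbtb_compound_rule()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  req <- c("pfam_accession", "family")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("rules table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$pfam_accession)) {
    stop("each pfam_accession must map to exactly one family; duplicated: ",
         df$pfam_accession[duplicated(df$pfam_accession)][1L])
  }
  if (is.null(df$superfamily)) df$superfamily <- NA_character_
  if (is.null(df$evalue_threshold)) df$evalue_threshold <- NA_real_
  if (is.null(df$is_dbd)) df$is_dbd <- 1L
  if (is.null(df$domain_name)) df$domain_name <- df$pfam_accession
  df$evalue_threshold <- as.numeric(df$evalue_threshold)
  if (any(!is.na(df$evalue_threshold) & df$evalue_threshold <= 0)) {
    stop("e-value thresholds must be > 0")
  }
  stopifnot_scalar_number(default_threshold, "default_threshold")
  if (default_threshold <= 0) stop("default_threshold must be > 0")
  structure(
    list(rules = df[, c("pfam_accession", "domain_name", "family",
                        "superfamily", "evalue_threshold", "is_dbd")],
         default_threshold = default_threshold,
         compound_rules = compound_rules),
    class = "family_rules"
  )
}

#' The ZBTB compound-domain rule
#'
#' A gene carrying passing hits from both the BTB family and the zf-C2H2
#' family is classified in the zf-C2H2 family with subtype ZBTB.
#'
#' @return One-row data frame with columns `subtype`, `required`
#'   (list column) and `host_family`.
#' @export
zbtb_compound_rule <- function() {
  data.frame(subtype = "ZBTB",
             required = I(list(c("BTB", "zf-C2H2"))),
             host_family = "zf-C2H2",
             stringsAsFactors = FALSE)
}

#' The packaged default DBD rule set
#'
#' Loads the curated default rules: 85 Pfam DNA-binding-domain accessions
#' covering the metazoan TF families surveyed by the package, plus the
#' BTB accessory domain used by the ZBTB compound rule. Threshold
#' overrides: bHLH `1e-2`; HMG_box, Homeodomain, zf-BED and zf-C2H2
#' `1e-3`; zf-CCCH `1e-20`; all other families use the `1e-4` default.
#'
#' @return An object of class `family_rules`.
#' @export
default_family_rules <- function() {
  path <- system.file("extdata", "tf_family_rules.tsv", package = "tfcensus",
                      mustWork = TRUE)
  read_family_rules(path)
}

#' @export
print.family_rules <- function(x, ...) {
  n_dbd <- sum(x$rules$is_dbd == 1L)
  cat("TF family rule set\n")
  cat("  accessions:", nrow(x$rules), sprintf("(%d DBD)", n_dbd), "\n")
  cat("  families:  ", length(unique(x$rules$family[x$rules$is_dbd == 1L])),
      "\n")
  cat("  default threshold:", format(x$default_threshold), "\n")
  ov <- x$rules[!is.na(x$rules$evalue_threshold), ]
  if (nrow(ov) > 0L) {
    fams <- tapply(ov$evalue_threshold, ov$family, unique)
    cat("  overrides: ",
        paste(sprintf("%s=%g", names(fams), unlist(fams)), collapse = ", "),
        "\n")
  }
  cat("  compound subtypes:",
      paste(x$compound_rules$subtype, collapse = ", "), "\n")
  invisible(x)
}

# effective threshold for each accession (override else default)
rule_thresholds <- function(rules) {
  t <- rules$rules$evalue_threshold
  t[is.na(t)] <- rules$default_threshold
  setNames(t, rules$rules$pfam_accession)
}

# family names reachable by DBD accessions (census universe)
dbd_families <- function(rules) {
  sort(unique(rules$rules$family[rules$rules$is_dbd == 1L]))
}

# family -> superfamily lookup (NA where none)
family_superfamily <- function(rules) {
  df <- unique(rules$rules[, c("family", "superfamily")])
  setNames(df$superfamily, df$family)
}
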