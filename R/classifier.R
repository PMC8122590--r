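## TF identification and family classification.
##
## A gene is called a TF when at least one of its DNA-binding-domain hits
## passes its family's e-value threshold. Family assignment is
## deterministic: compound-domain rules first (e.g. BTB + zf-C2H2 ->
## zf-C2H2/ZBTB), then the passing hit with the smallest e-value, ties
## broken by larger bit score, then alphabetical family name.

#' Filter domain hits by per-family e-value thresholds
#'
#' Retains exactly the hits whose e-value is less than or equal to the
#' threshold of the family their Pfam accession maps to (per-family
#' override if present, else the rule set's default). Hits on accessions
#' absent from the rule set are dropped silently, as are non-DBD hits
#' whose accession is not part of any rule. The boundary is inclusive:
#' an e-value exactly equal to its threshold passes.
#'
#' @param hits domain hit table (see [read_domtblout()]).
#' @param rules a `family_rules` object.
#' @param evalue_field which hmmscan e-value to screen: the full-sequence
#'   e-value (default, the convention of the TF databases the thresholds
#'   are borrowed from) or the per-domain independent e-value.
#' @return The passing subset of `hits`, with columns `family`,
#'   `superfamily` and `is_dbd` appended.
#' @export
apply_thresholds <- function(hits, rules,
                             evalue_field = c("full_seq", "ind_domain")) {
  evalue_field <- match.arg(evalue_field)
  validate_domain_hits(hits)
  known <- hits$pfam_accession %in% rules$rules$pfam_accession
  hits <- hits[known, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- hits
    out$family <- character(0)
    out$superfamily <- character(0)
    out$is_dbd <- integer(0)
    return(out)
  }
  idx <- match(hits$pfam_accession, rules$rules$pfam_accession)
  thr <- rule_thresholds(rules)[hits$pfam_accession]
  ev <- if (evalue_field == "full_seq") hits$full_seq_evalue else
    hits$ind_domain_evalue
  keep <- ev <= thr
  out <- hits[keep, , drop = FALSE]
  out$family <- rules$rules$family[idx][keep]
  out$superfamily <- rules$rules$superfamily[idx][keep]
  out$is_dbd <- rules$rules$is_dbd[idx][keep]
  rownames(out) <- NULL
  out
}

#' Assign a TF family to one gene from its passing hits
#'
#' Resolution order for genes with passing hits from several families:
#' \enumerate{
#'   \item Compound rules: if the gene carries passing hits from every
#'     required family of a compound rule (e.g. BTB and zf-C2H2), the
#'     gene is assigned to the rule's host family with the rule's
#'     subtype.
#'   \item Otherwise, the DBD family of the passing hit with the smallest
#'     e-value wins; ties are broken by larger bit score, then by
#'     alphabetical family name.
#' }
#' A gene whose passing hits are all on accessory (non-DBD) domains is
#' not a TF and yields `NULL`. All passing DBD families are recorded in
#' `candidate_families` as an audit trail.
#'
#' @param gene_id the gene the hits belong to.
#' @param passing_hits output of [apply_thresholds()] restricted to this
#'   gene's proteins; an error is raised if hits span several genes (pass
#'   hits through [classify_proteome()] for whole proteomes).
#' @param rules a `family_rules` object.
#' @param evalue_field see [apply_thresholds()].
#' @return A one-row data frame with columns `gene_id`, `family`,
#'   `superfamily`, `subtype`, `best_evalue`, `n_passing_hits` and the
#'   list column `candidate_families`, or `NULL` when no DBD hit passes.
#' @export
assign_family <- function(gene_id, passing_hits, rules,
                          evalue_field = c("full_seq", "ind_domain")) {
  evalue_field <- match.arg(evalue_field)
  if (is.null(passing_hits) || nrow(passing_hits) == 0L) return(NULL)
  if (!is.null(passing_hits$gene_id) &&
      length(unique(passing_hits$gene_id)) > 1L) {
    stop("assign_family(): hits span multiple gene_ids (",
         paste(unique(passing_hits$gene_id), collapse = ", "), ")")
  }
  ev <- if (evalue_field == "full_seq") passing_hits$full_seq_evalue else
    passing_hits$ind_domain_evalue
  fams_all <- unique(passing_hits$family)
  dbd <- passing_hits$is_dbd == 1L
  candidates <- sort(unique(passing_hits$family[dbd]))
  if (length(candidates) == 0L) return(NULL)

  family <- NULL
  subtype <- NA_character_
  for (i in seq_len(nrow(rules$compound_rules))) {
    required <- rules$compound_rules$required[[i]]
    if (all(required %in% fams_all)) {
      family <- rules$compound_rules$host_family[i]
      subtype <- rules$compound_rules$subtype[i]
      break
    }
  }
  if (is.null(family)) {
    dh <- passing_hits[dbd, , drop = FALSE]
    dev <- ev[dbd]
    ord <- order(dev, -dh$bit_score, dh$family)
    family <- dh$family[ord[1L]]
  }
  sf <- family_superfamily(rules)[family]
  best <- if (any(passing_hits$family == family)) {
    min(ev[passing_hits$family == family])
  } else min(ev)
  out <- data.frame(gene_id = gene_id, family = family,
                    superfamily = unname(sf), subtype = subtype,
                    best_evalue = best,
                    n_passing_hits = nrow(passing_hits),
                    stringsAsFactors = FALSE)
  out$candidate_families <- I(list(candidates))
  out
}

#' Classify a whole proteome into TF families
#'
#' Composes the full identification pipeline: one representative protein
#' per gene ([select_longest_isoform()]), e-value screening against the
#' rule set ([apply_thresholds()]) and per-gene family assignment
#' ([assign_family()]). Counting is per gene: hits on non-representative
#' isoforms are ignored.
#'
#' @param hits domain hit table for the proteome.
#' @param proteins protein record table (`protein_id`, `gene_id`,
#'   `sequence_length`).
#' @param rules a `family_rules` object (default: the packaged rule set).
#' @param evalue_field see [apply_thresholds()].
#' @return Data frame of TF assignments, one row per TF gene, ordered by
#'   `gene_id` (see [assign_family()] for columns).
#' @export
classify_proteome <- function(hits, proteins, rules = default_family_rules(),
                              evalue_field = c("full_seq", "ind_domain")) {
  evalue_field <- match.arg(evalue_field)
  unknown <- setdiff(hits$protein_id, proteins$protein_id)
  if (length(unknown) > 0L) {
    stop("hits reference protein(s) absent from the proteome: ",
         paste(head(unknown, 3L), collapse = ", "))
  }
  reps <- select_longest_isoform(proteins)
  hits <- hits[hits$protein_id %in% reps$protein_id, , drop = FALSE]
  passing <- apply_thresholds(hits, rules, evalue_field)
  if (nrow(passing) == 0L) return(empty_assignments())
  passing$gene_id <- reps$gene_id[match(passing$protein_id, reps$protein_id)]
  pieces <- split(passing, passing$gene_id)
  rows <- lapply(names(pieces), function(g) {
    assign_family(g, pieces[[g]], rules, evalue_field)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(empty_assignments())
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_assignments <- function() {
  out <- data.frame(gene_id = character(), family = character(),
                    superfamily = character(), subtype = character(),
                    best_evalue = numeric(), n_passing_hits = integer(),
                    stringsAsFactors = FALSE)
  out$candidate_families <- I(list())
  out
}

#' Count assignments carrying a given subtype
#'
#' @param assignments output of [classify_proteome()].
#' @param subtype_name subtype label, e.g. `"ZBTB"`.
#' @return Non-negative integer count.
#' @export
count_subtype <- function(assignments, subtype_name) {
  sum(!is.na(assignments$subtype) & assignments$subtype == subtype_name)
}
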