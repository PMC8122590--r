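## Seeded generators for every input the pipeline consumes, with known
## ground truth. Each generator is a pure function of its arguments
## (including the seed): the same call yields identical truth tables and
## identical emitted files. The caller's RNG state is left untouched.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# default planted family composition: proportional to a realistic
# tunicate TF repertoire (the packaged per-family counts)
default_family_mix <- function(rules) {
  pt <- load_paper_tables()
  counts <- pt$table1[, "S. clava"]
  counts <- counts[names(counts) %in% dbd_families(rules) & counts > 0]
  counts / sum(counts)
}

#' Simulate a proteome with planted TF domain architectures
#'
#' Plants `n_tf` TF genes whose DNA-binding-domain hits pass their
#' family's e-value threshold (e-values drawn log-uniformly below the
#' threshold), of which the first `n_compound` carry both a passing BTB
#' and a passing zf-C2H2 domain (the ZBTB architecture). `n_decoys`
#' decoy genes receive only sub-threshold hits, kept at least 10x above
#' their family threshold so that boundary conventions cannot flip their
#' outcome. Every gene gets 1-4 isoforms of distinct lengths; only the
#' longest isoform carries the hits.
#'
#' @param n_tf number of planted TF genes (including compound genes).
#' @param family_mix named numeric vector of planted-family proportions
#'   (summing to 1) for the non-compound TF genes; default: proportional
#'   to the packaged per-family counts.
#' @param n_decoys number of decoy genes.
#' @param n_compound number of planted ZBTB (BTB + zf-C2H2) genes among
#'   `n_tf`.
#' @param seed integer seed.
#' @param rules `family_rules` the families are drawn from.
#' @param dir optional directory; when given, `hits.domtblout`,
#'   `proteome.fasta` and `truth.tsv` are written there.
#' @return List with `hits` (domain hit table), `proteins` (protein
#'   record table), `truth` (data frame `gene_id`, `role`, `family`,
#'   `subtype`) and, when `dir` is given, `files`.
#' @export
simulate_domtblout <- function(n_tf = 120L, family_mix = NULL,
                               n_decoys = 80L, n_compound = 12L,
                               seed, rules = default_family_rules(),
                               dir = NULL) {
  if (n_compound > n_tf) stop("n_compound cannot exceed n_tf")
  if (is.null(family_mix)) family_mix <- default_family_mix(rules)
  unknown <- setdiff(names(family_mix), dbd_families(rules))
  if (length(unknown) > 0L) {
    stop("family_mix names not in the rule set: ",
         paste(unknown, collapse = ", "))
  }
  if (abs(sum(family_mix) - 1) > 1e-8) {
    stop("family_mix proportions must sum to 1")
  }
  thr <- rule_thresholds(rules)
  # one representative DBD accession per family
  dbd_rows <- rules$rules[rules$rules$is_dbd == 1L, ]
  fam_acc <- tapply(dbd_rows$pfam_accession, dbd_rows$family,
                    function(a) sort(a)[1L])
  name_of <- setNames(rules$rules$domain_name, rules$rules$pfam_accession)

  with_seed(seed, {
    n_plain <- n_tf - n_compound
    plain_fams <- if (n_plain > 0L) {
      sample(names(family_mix), n_plain, replace = TRUE, prob = family_mix)
    } else character(0)
    truth <- data.frame(
      gene_id = c(sprintf("tf%04d", seq_len(n_tf)),
                  sprintf("decoy%04d", seq_len(n_decoys))),
      role = c(rep("tf", n_tf), rep("decoy", n_decoys)),
      family = c(rep("zf-C2H2", n_compound), plain_fams,
                 rep(NA_character_, n_decoys)),
      subtype = c(rep("ZBTB", n_compound),
                  rep(NA_character_, n_plain + n_decoys)),
      stringsAsFactors = FALSE)

    passing_e <- function(fam) {
      10^runif(1L, log10(thr[fam_acc[fam]]) - 20, log10(thr[fam_acc[fam]]))
    }
    failing_e <- function(acc) 10^runif(1L, log10(thr[acc]) + 1,
                                        log10(thr[acc]) + 5)
    one_hit <- function(protein, acc, name, e, plen) {
      st <- sample.int(max(plen - 60L, 1L), 1L)
      data.frame(protein_id = protein, pfam_accession = unname(acc),
                 domain_name = unname(name), full_seq_evalue = unname(e),
                 ind_domain_evalue = unname(e) * 10^runif(1L, 0, 1),
                 bit_score = round(runif(1L, 20, 300), 1L),
                 env_start = st, env_end = min(st + 49L, plen),
                 stringsAsFactors = FALSE)
    }

    proteins <- list()
    hits <- list()
    btb_acc <- rules$rules$pfam_accession[rules$rules$family == "BTB"][1L]
    all_dbd_acc <- dbd_rows$pfam_accession
    for (i in seq_len(nrow(truth))) {
      g <- truth$gene_id[i]
      n_iso <- sample.int(4L, 1L)
      lens <- sort(sample(150:1200, n_iso))  # distinct, last is longest
      iso_ids <- sprintf("%s.p%d", g, seq_len(n_iso))
      proteins[[i]] <- data.frame(protein_id = iso_ids, gene_id = g,
                                  sequence_length = lens,
                                  stringsAsFactors = FALSE)
      rep_prot <- iso_ids[n_iso]
      plen <- lens[n_iso]
      if (truth$role[i] == "tf") {
        if (!is.na(truth$subtype[i]) && truth$subtype[i] == "ZBTB") {
          hits[[length(hits) + 1L]] <- one_hit(
            rep_prot, btb_acc, name_of[btb_acc],
            10^runif(1L, log10(thr[btb_acc]) - 20, log10(thr[btb_acc])),
            plen)
          hits[[length(hits) + 1L]] <- one_hit(
            rep_prot, fam_acc["zf-C2H2"], name_of[fam_acc["zf-C2H2"]],
            passing_e("zf-C2H2"), plen)
        } else {
          fam <- truth$family[i]
          hits[[length(hits) + 1L]] <- one_hit(
            rep_prot, fam_acc[fam], name_of[fam_acc[fam]],
            passing_e(fam), plen)
          if (runif(1L) < 0.3) {  # sub-threshold bystander hit
            acc <- sample(all_dbd_acc, 1L)
            hits[[length(hits) + 1L]] <- one_hit(
              rep_prot, acc, name_of[acc], failing_e(acc), plen)
          }
        }
      } else {
        for (j in seq_len(sample.int(3L, 1L))) {
          acc <- sample(all_dbd_acc, 1L)
          hits[[length(hits) + 1L]] <- one_hit(rep_prot, acc, name_of[acc],
                                               failing_e(acc), plen)
        }
      }
    }
    proteins <- do.call(rbind, proteins)
    hits <- do.call(rbind, hits)
    rownames(proteins) <- rownames(hits) <- NULL

    out <- list(hits = hits, proteins = proteins, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      f_dom <- file.path(dir, "hits.domtblout")
      f_fa <- file.path(dir, "proteome.fasta")
      f_truth <- file.path(dir, "truth.tsv")
      write_domtblout(hits, f_dom)
      seqs <- vapply(proteins$sequence_length, function(L)
        paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
        character(1L))
      aa <- Biostrings::AAStringSet(seqs)
      names(aa) <- sprintf("%s gene=%s", proteins$protein_id,
                           proteins$gene_id)
      Biostrings::writeXStringSet(aa, f_fa)
      write.table(truth, f_truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$files <- c(domtblout = f_dom, fasta = f_fa, truth = f_truth)
    }
    out
  })
}

#' Simulate stage-peaked expression with planted modules
#'
#' Each module shares a latent log10-scale profile: a Gaussian bump (on
#' the 7-stage axis) centered at its peak stage, to which independent
#' per-gene noise is added so that the expected within-module Pearson
#' correlation equals `within_correlation`. Genes beyond the module
#' sizes are unstructured background. FPKM is `10^profile - 1`, clipped
#' at 0, so that log10(FPKM + 1) normalization recovers the latent
#' structure exactly up to clipping.
#'
#' @param n_genes total genes; module sizes must sum to at most this.
#' @param module_spec list of `list(size, peak_stage,
#'   within_correlation)` entries, `within_correlation` in (0, 1].
#' @param noise_sd replicate-level measurement noise on the log scale
#'   (default 0.05).
#' @param replicates replicate libraries per stage (default 3).
#' @param peak_width standard deviation of the Gaussian bump in stage
#'   units (default 0.6: expression concentrated in one to two stages,
#'   so distinct planted modules are mutually near-orthogonal).
#' @param seed integer seed.
#' @param dir optional directory to write `expression.tsv` (replicate
#'   columns) and `truth.tsv`.
#' @return List with `expr` (stage-level FPKM matrix), `replicate_expr`
#'   (genes x stage-replicate FPKM), `truth` (data frame `gene_id`,
#'   `module` index with 0 = background, `peak_stage`) and optional
#'   `files`.
#' @export
simulate_expression <- function(n_genes, module_spec, noise_sd = 0.05,
                                replicates = 3L, peak_width = 0.6,
                                seed, dir = NULL) {
  stages <- dev_stages()
  sizes <- vapply(module_spec, function(m) as.integer(m$size), integer(1L))
  peaks <- vapply(module_spec, function(m) as.character(m$peak_stage),
                  character(1L))
  rr <- vapply(module_spec, function(m) as.numeric(m$within_correlation),
               numeric(1L))
  if (any(!peaks %in% stages)) {
    stop("invalid peak stage(s): ",
         paste(setdiff(peaks, stages), collapse = ", "))
  }
  if (any(rr <= 0 | rr > 1)) stop("within_correlation must be in (0, 1]")
  if (sum(sizes) > n_genes) stop("module sizes exceed n_genes")

  axis <- seq_along(stages)
  baseline <- 0.2
  amplitude <- 2
  latent <- lapply(match(peaks, stages), function(p)
    baseline + amplitude * exp(-(axis - p)^2 / (2 * peak_width^2)))

  with_seed(seed, {
    n_bg <- n_genes - sum(sizes)
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    module_of <- rep(c(seq_along(sizes), 0L), times = c(sizes, n_bg))
    logm <- matrix(0, n_genes, length(stages),
                   dimnames = list(gene_ids, stages))
    for (i in seq_len(n_genes)) {
      m <- module_of[i]
      if (m == 0L) {
        logm[i, ] <- baseline + rnorm(length(stages), 0, 0.5)
      } else {
        f <- latent[[m]]
        sd_f <- stats::sd(f)
        sd_noise <- sd_f * sqrt((1 - rr[m]) / rr[m])
        logm[i, ] <- f + rnorm(length(stages), 0, sd_noise)
      }
    }
    expr <- pmax(10^logm - 1, 0)
    rep_cols <- as.vector(outer(stages, seq_len(replicates),
                                function(s, k) paste0(s, "_", k)))
    rep_log <- logm[, rep(seq_along(stages), each = replicates),
                    drop = FALSE] +
      rnorm(n_genes * length(stages) * replicates, 0, noise_sd)
    colnames(rep_log) <- as.vector(vapply(stages, function(s)
      paste0(s, "_", seq_len(replicates)), character(replicates)))
    replicate_expr <- pmax(10^rep_log - 1, 0)

    truth <- data.frame(gene_id = gene_ids, module = module_of,
                        peak_stage = c(peaks, NA_character_)[
                          ifelse(module_of == 0L, length(peaks) + 1L,
                                 module_of)],
                        stringsAsFactors = FALSE)
    out <- list(expr = expr, replicate_expr = replicate_expr, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      f_expr <- file.path(dir, "expression.tsv")
      f_truth <- file.path(dir, "truth.tsv")
      write_expression_table(replicate_expr, f_expr)
      write.table(truth, f_truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$files <- c(expression = f_expr, truth = f_truth)
    }
    out
  })
}

#' Simulate a Hox-like gene cluster with a planted onset pattern
#'
#' Places `n_genes` cluster genes in order on one chromosome and plants
#' expression onsets that are collinear with genomic order (`forward`),
#' exactly reversed (`reverse`), or a rejection-sampled permutation
#' containing no perfectly collinear window of length 3 or more
#' (`shuffled`).
#'
#' @param n_genes cluster size (at most 7 for `forward`/`reverse`, so
#'   onsets can be strictly ordered over the seven stages).
#' @param orientation `"forward"`, `"reverse"` or `"shuffled"`.
#' @param seed integer seed.
#' @param dir optional directory to write `cluster.bed`, `pg.tsv`,
#'   `expression.tsv` and `truth.tsv`.
#' @return List with `loci` (BED-convention data frame), `pg` (data
#'   frame `gene_id`, `pg`, `chromosome`), `expr` (FPKM matrix), `truth`
#'   (`gene_id`, `onset`) and optional `files`.
#' @export
simulate_hox_cluster <- function(n_genes = 7L,
                                 orientation = c("forward", "reverse",
                                                 "shuffled"),
                                 seed, dir = NULL) {
  orientation <- match.arg(orientation)
  stages <- dev_stages()
  if (orientation != "shuffled" && n_genes > length(stages)) {
    stop("strictly collinear onsets need n_genes <= ", length(stages))
  }
  if (n_genes < 3L) stop("need at least 3 cluster genes")

  with_seed(seed, {
    gene_ids <- sprintf("hox%d", seq_len(n_genes))
    loci <- data.frame(gene_id = gene_ids, chromosome = "chr1",
                       start = (seq_len(n_genes) - 1L) * 10000L,
                       end = (seq_len(n_genes) - 1L) * 10000L + 2000L,
                       strand = "+", stringsAsFactors = FALSE)
    pg <- data.frame(gene_id = gene_ids, pg = seq_len(n_genes),
                     chromosome = "chr1", stringsAsFactors = FALSE)
    onset_idx <- switch(orientation,
      forward = seq_len(n_genes),
      reverse = rev(seq_len(n_genes)),
      shuffled = {
        ok <- FALSE
        idx <- NULL
        for (try in seq_len(1000L)) {
          idx <- sample(seq_along(stages), n_genes,
                        replace = n_genes > length(stages))
          probe <- data.frame(gene_id = gene_ids, onset = stages[idx],
                              stringsAsFactors = FALSE)
          if (nrow(find_collinear_subclusters(probe)) == 0L) {
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not shuffle onsets without a collinear window")
        idx
      })
    onsets <- stages[onset_idx]
    expr <- matrix(0.5, n_genes, length(stages),
                   dimnames = list(gene_ids, stages))
    for (i in seq_len(n_genes)) {
      expr[i, onset_idx[i]:length(stages)] <- 50
    }
    truth <- data.frame(gene_id = gene_ids, onset = onsets,
                        stringsAsFactors = FALSE)
    out <- list(loci = loci, pg = pg, expr = expr, truth = truth,
                orientation = orientation)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      f_bed <- file.path(dir, "cluster.bed")
      f_pg <- file.path(dir, "pg.tsv")
      f_expr <- file.path(dir, "expression.tsv")
      f_truth <- file.path(dir, "truth.tsv")
      bed <- data.frame(loci$chromosome, loci$start, loci$end,
                        loci$gene_id, 0L, loci$strand)
      write.table(bed, f_bed, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      write.table(pg, f_pg, sep = "\t", quote = FALSE, row.names = FALSE)
      write_expression_table(expr, f_expr)
      write.table(truth, f_truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$files <- c(bed = f_bed, pg = f_pg, expression = f_expr,
                     truth = f_truth)
    }
    out
  })
}

#' Simulate gene-term annotations with one planted enriched term
#'
#' Assigns `n_terms - 1` decoy terms to genes independently of target
#' membership (each with probability `base_prob`) and one planted term
#' whose probability in the target set is `enriched_term_fold` times
#' `base_prob`.
#'
#' @param n_genes background size.
#' @param n_terms total terms including the planted one.
#' @param enriched_term_fold over-representation factor of the planted
#'   term in the target set; `enriched_term_fold * base_prob` must not
#'   exceed 1.
#' @param target_fraction fraction of genes in the target set.
#' @param base_prob per-gene annotation probability of each term
#'   (default 0.08).
#' @param seed integer seed.
#' @param dir optional directory to write `annotations.tsv`,
#'   `target.txt` and `truth.tsv`.
#' @return List with `annotations` (`gene_id`, `term_id`), `target`,
#'   `background`, `truth` (`planted_term`, `fold`) and optional
#'   `files`.
#' @export
simulate_annotation <- function(n_genes = 500L, n_terms = 51L,
                                enriched_term_fold = 5,
                                target_fraction = 0.3,
                                base_prob = 0.08, seed, dir = NULL) {
  p1 <- enriched_term_fold * base_prob
  if (p1 > 1) stop("infeasible fold: enriched probability exceeds 1")
  if (n_terms < 1L) stop("need at least the planted term")
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    target <- sort(sample(genes, round(target_fraction * n_genes)))
    planted <- "T_planted"
    decoys <- sprintf("T%03d", seq_len(n_terms - 1L))
    ann <- list()
    p_planted <- ifelse(genes %in% target, p1, base_prob)
    has <- runif(n_genes) < p_planted
    if (any(has)) {
      ann[[1L]] <- data.frame(gene_id = genes[has], term_id = planted,
                              stringsAsFactors = FALSE)
    }
    for (tm in decoys) {
      has <- runif(n_genes) < base_prob
      if (any(has)) {
        ann[[length(ann) + 1L]] <- data.frame(gene_id = genes[has],
                                              term_id = tm,
                                              stringsAsFactors = FALSE)
      }
    }
    annotations <- do.call(rbind, ann)
    rownames(annotations) <- NULL
    truth <- list(planted_term = planted, fold = enriched_term_fold)
    out <- list(annotations = annotations, target = target,
                background = genes, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      f_ann <- file.path(dir, "annotations.tsv")
      f_tgt <- file.path(dir, "target.txt")
      f_truth <- file.path(dir, "truth.tsv")
      write.table(annotations, f_ann, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      writeLines(target, f_tgt)
      write.table(data.frame(planted_term = planted,
                             fold = enriched_term_fold),
                  f_truth, sep = "\t", quote = FALSE, row.names = FALSE)
      out$files <- c(annotations = f_ann, target = f_tgt, truth = f_truth)
    }
    out
  })
}
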