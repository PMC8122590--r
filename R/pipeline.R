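## End-to-end orchestration: classify -> census -> modules -> hox ->
## enrich from a validated configuration, with TSV outputs and a
## machine-readable run manifest.

#' Build and validate a pipeline configuration
#'
#' All paths are checked for existence at validation time; parameters
#' are checked against their documented ranges. Only the stages whose
#' inputs are supplied are run.
#'
#' @param domtblout,proteins paths to an hmmscan per-domain table and a
#'   protein FASTA (classification stage).
#' @param rules path to a family rules TSV, or `NULL` for the packaged
#'   default rule set.
#' @param expression path to a gene-by-stage FPKM TSV (module stage).
#' @param hox_bed,hox_pg paths to a BED of cluster loci and a
#'   gene-to-paralog-group TSV (Hox stage; uses `expression` for
#'   onsets).
#' @param annotations,target paths to a gene/term TSV and a target gene
#'   list (enrichment stage).
#' @param power,min_module_size,cut_height,network_sign module-detection
#'   parameters (see [tf_coexpression()]).
#' @param expressed_threshold FPKM cutoff for expressed-gene and onset
#'   calls (default 10).
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(domtblout = NULL, proteins = NULL, rules = NULL,
                            expression = NULL, hox_bed = NULL,
                            hox_pg = NULL, annotations = NULL,
                            target = NULL, power = 12,
                            min_module_size = 300, cut_height = 0.99,
                            network_sign = "unsigned",
                            expressed_threshold = 10, seed = 1L) {
  paths <- c(domtblout = domtblout, proteins = proteins, rules = rules,
             expression = expression, hox_bed = hox_bed, hox_pg = hox_pg,
             annotations = annotations, target = target)
  missing <- paths[!vapply(paths, file.exists, logical(1L))]
  if (length(missing) > 0L) {
    stop("configured path(s) do not exist: ",
         paste(sprintf("%s=%s", names(missing), missing), collapse = ", "))
  }
  if (power < 1) stop("power must be >= 1")
  if (min_module_size < 1) stop("min_module_size must be >= 1")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]")
  if (!network_sign %in% c("unsigned", "signed")) {
    stop("network_sign must be 'unsigned' or 'signed'")
  }
  structure(list(paths = as.list(paths), power = power,
                 min_module_size = min_module_size,
                 cut_height = cut_height, network_sign = network_sign,
                 expressed_threshold = expressed_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configurations requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  path_keys <- c("domtblout", "proteins", "rules", "expression", "hox_bed",
                 "hox_pg", "annotations", "target")
  base <- dirname(normalizePath(path))
  for (k in intersect(path_keys, names(raw))) {
    if (!startsWith(raw[[k]], "/")) raw[[k]] <- file.path(base, raw[[k]])
  }
  do.call(pipeline_config, raw)
}

#' Run the configured pipeline stages
#'
#' Runs every stage whose inputs are configured, writes each stage's
#' output as TSV under `out_dir`, and writes `manifest.json` recording
#' package version, parameters and input checksums. Outputs are
#' deterministic for a fixed configuration. A stage failure aborts the
#' run with the failing stage named; a `FAILED` marker file is left next
#' to any partial outputs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return A list of stage results (`assignments`, `census`, `fit`,
#'   `family_modules`, `stc`, `enrichment` as applicable), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$paths
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  rules <- if (!is.null(p$rules)) read_family_rules(p$rules) else
    default_family_rules()

  if (!is.null(p$domtblout) && !is.null(p$proteins)) {
    results$assignments <- stage("classify", {
      hits <- read_domtblout(p$domtblout)
      prot <- read_protein_fasta(p$proteins)
      a <- classify_proteome(hits, prot, rules)
      flat <- a
      flat$candidate_families <- vapply(a$candidate_families, paste,
                                        character(1L), collapse = ";")
      write.table(flat, file.path(out_dir, "assignments.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      a
    })
    results$census <- stage("census", {
      m <- build_count_matrix(list(sample = results$assignments), rules)
      write.table(data.frame(family = rownames(m), m, check.names = FALSE),
                  file.path(out_dir, "family_counts.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      m
    })
  }

  expr <- NULL
  if (!is.null(p$expression)) {
    expr <- stage("read_expression", read_expression_table(p$expression))
  }

  if (!is.null(expr)) {
    results$fit <- stage("modules", {
      fit <- tf_coexpression(expr, power = config$power,
                             min_module_size = config$min_module_size,
                             cut_height = config$cut_height,
                             network_sign = config$network_sign)
      part <- fit$partition
      df <- data.frame(gene_id = part$gene_ids,
                       module = unname(part$module[part$gene_ids]),
                       group = unname(ifelse(
                         part$module[part$gene_ids] == "grey", NA,
                         part$group[part$module[part$gene_ids]])),
                       stringsAsFactors = FALSE)
      write.table(df, file.path(out_dir, "modules.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      fit
    })
    if (!is.null(results$assignments)) {
      results$family_modules <- stage("family_modules", {
        part <- results$fit$partition
        covered <- names(part$module)[part$module != "grey"] %in%
          results$assignments$gene_id
        if (all(covered)) {
          fm <- family_module_table(part, results$assignments)
          write.table(data.frame(family = rownames(fm), fm,
                                 check.names = FALSE),
                      file.path(out_dir, "family_modules.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          fm
        } else NULL
      })
    }
  }

  if (!is.null(p$hox_bed) && !is.null(p$hox_pg) && !is.null(expr)) {
    results$stc <- stage("hox", {
      loci <- read_bed_loci(p$hox_bed)
      loci <- loci[order(loci$chromosome, loci$start), , drop = FALSE]
      onsets <- onset_stages(expr[loci$gene_id, , drop = FALSE],
                             config$expressed_threshold)
      cluster <- data.frame(gene_id = loci$gene_id,
                            onset = unname(onsets[loci$gene_id]),
                            stringsAsFactors = FALSE)
      stc <- find_collinear_subclusters(cluster)
      flat <- stc
      flat$genes <- vapply(stc$genes, paste, character(1L), collapse = ";")
      write.table(flat, file.path(out_dir, "stc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      stc
    })
  }

  if (!is.null(p$annotations) && !is.null(p$target) &&
      !is.null(results$assignments)) {
    results$enrichment <- stage("enrich", {
      ann <- read.delim(p$annotations, stringsAsFactors = FALSE)
      target <- readLines(p$target)
      res <- enrich(target, results$assignments$gene_id, ann)
      write.table(res, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      res
    })
  }

  inputs <- unlist(p[!vapply(p, is.null, logical(1L))])
  manifest <- list(
    package = "tfcensus",
    version = as.character(utils::packageVersion("tfcensus")),
    parameters = config[setdiff(names(config), "paths")],
    inputs = as.list(tools::md5sum(inputs)),
    stages = names(results)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Recompute the published fixture-derivable numbers
#'
#' Recomputes, from the packaged tables, every reported quantity that is
#' derivable from them — totals, family fractions, shared and exclusive
#' family sets, expansions, orphan counts, module column and row sums,
#' and the maternally-expressed proportion — and compares each against
#' its printed value.
#'
#' @return Data frame with columns `check`, `expected`, `value`, `pass`.
#' @export
paper_checks <- function() {
  pt <- load_paper_tables()
  t1 <- pt$table1
  asc <- c("S. clava", "C. robusta", "M. oculata", "B. leachii",
           "B. schlosseri")
  four <- c("S. clava", "H. sapiens", "B. floridae", "C. elegans")
  ex <- exclusive_shared(t1, four, asc)
  checks <- list(
    list("S. clava total TFs", 553, total_tfs(t1, "S. clava")),
    list("S. clava total TF families", 60, total_families(t1, "S. clava")),
    list("zf-C2H2 fraction of S. clava TFs (%)", 27.85,
         family_fraction(t1, "zf-C2H2", "S. clava")),
    list("Homeodomain fraction of S. clava TFs (%)", 13.20,
         family_fraction(t1, "Homeodomain", "S. clava")),
    list("S. clava orphan families", 16,
         length(orphan_families(t1, "S. clava"))),
    list("families shared by the four chordate outgroup species", 51,
         length(shared_families(t1, four))),
    list("families shared by the five ascidians", 51,
         length(shared_families(t1, asc))),
    list("families shared between the two groups", 44,
         length(ex$common)),
    list("families exclusive to the chordate comparison", 7,
         length(ex$only_a)),
    list("families exclusive to the ascidian comparison", 7,
         length(ex$only_b)),
    list("zf-C2H2 expansion vs O. dioica", 82,
         family_expansion(t1, "zf-C2H2", "S. clava", "O. dioica")),
    list("zf-C2H2 expansion vs B. leachii", 44,
         family_expansion(t1, "zf-C2H2", "S. clava", "B. leachii")),
    list("turquoise module size", 174, sum(pt$table2[, "turquoise"])),
    list("Forkhead box genes across modules", 23,
         sum(pt$table2["Forkhead box", ])),
    list("maternally expressed TF proportion (%)", 52.44,
         round(100 * 290 / 553, 2))
  )
  out <- data.frame(
    check = vapply(checks, `[[`, character(1L), 1L),
    expected = vapply(checks, `[[`, numeric(1L), 2L),
    value = vapply(checks, function(x) as.numeric(x[[3L]]), numeric(1L)),
    stringsAsFactors = FALSE)
  out$pass <- out$expected == out$value
  out
}
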