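## Weighted co-expression network over developmental stages, implemented
## from first principles: log10(FPKM + 1) normalization, Pearson
## correlation across stages, soft-threshold adjacency a_ij = |c_ij|^beta
## (or signed ((1 + c_ij)/2)^beta), topological overlap
##   TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
##   l_ij = sum_{u != i,j} a_iu a_uj,   k_i = sum_{u != i} a_iu,
## average-linkage clustering on 1 - TOM with a static height cut, and
## size-ranked module colors.

# module colors by descending size, the conventional ranking
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' log10(FPKM + 1) normalization
#'
#' @param matrix non-negative numeric matrix (genes x stages).
#' @return Matrix of the same shape with `log10(x + 1)` applied
#'   elementwise.
#' @export
normalize_log10 <- function(matrix) {
  if (any(matrix < 0)) stop("FPKM values must be non-negative")
  log10(matrix + 1)
}

#' Expressed-gene call at one stage
#'
#' A gene is called expressed at a stage when its FPKM is strictly above
#' `threshold` (default 10) there.
#'
#' @param matrix genes x stages FPKM matrix with dimnames.
#' @param stage stage (column) name.
#' @param threshold FPKM cutoff; strictly-greater comparison.
#' @return Character vector of expressed gene ids.
#' @export
call_expressed <- function(matrix, stage, threshold = 10) {
  if (!stage %in% colnames(matrix)) stop("unknown stage: ", stage)
  rownames(matrix)[matrix[, stage] > threshold]
}

#' Proportion of a gene universe expressed at one stage
#'
#' @param matrix genes x stages FPKM matrix.
#' @param stage stage name.
#' @param universe_size positive denominator (e.g. the total number of
#'   TF genes).
#' @param threshold FPKM cutoff (default 10).
#' @param digits decimals for the reported percentage (default 2).
#' @return Percentage, `100 * n_expressed / universe_size`.
#' @export
expressed_proportion <- function(matrix, stage, universe_size,
                                 threshold = 10, digits = 2L) {
  if (universe_size <= 0) stop("universe_size must be positive")
  round(100 * length(call_expressed(matrix, stage, threshold)) /
          universe_size, digits)
}

#' Gene-gene Pearson correlation across stages
#'
#' Correlations are computed across the stage columns of a
#' (log-normalized) expression matrix. Genes with zero variance across
#' stages get correlation 0 to every other gene and are flagged in the
#' `"zero_variance"` attribute of the result.
#'
#' @param matrix genes x stages numeric matrix with at least 3 columns.
#' @return Symmetric correlation matrix with unit diagonal;
#'   `attr(, "zero_variance")` lists flat genes.
#' @export
correlation_matrix <- function(matrix) {
  if (ncol(matrix) < 3L) {
    stop("need at least 3 stage columns to correlate profiles")
  }
  sds <- apply(matrix, 1L, stats::sd)
  C <- suppressWarnings(cor(t(matrix)))
  zv <- sds == 0
  if (any(zv)) {
    C[zv, ] <- 0
    C[, zv] <- 0
  }
  diag(C) <- 1
  attr(C, "zero_variance") <- rownames(matrix)[zv]
  C
}

#' Soft-threshold adjacency
#'
#' Unsigned: `a_ij = |c_ij|^power`; signed:
#' `a_ij = ((1 + c_ij)/2)^power`. The diagonal is 1.
#'
#' @param C symmetric correlation matrix.
#' @param power soft-threshold exponent beta (>= 1; default 12).
#' @param network_sign `"unsigned"` (default) or `"signed"`.
#' @return Adjacency matrix in `[0, 1]`.
#' @export
soft_adjacency <- function(C, power = 12, network_sign = c("unsigned",
                                                           "signed")) {
  network_sign <- match.arg(network_sign)
  if (power < 1) stop("soft power must be >= 1")
  A <- if (network_sign == "unsigned") abs(C)^power else ((1 + C) / 2)^power
  diag(A) <- 1
  A
}

#' Topological overlap matrix
#'
#' Computes `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij` the shared-neighbor weight and `k_i` the connectivity, via one
#' matrix product. The diagonal is set to 1.
#'
#' @param A adjacency matrix in `[0, 1]` with unit diagonal.
#' @return Symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
compute_tom <- function(A) {
  if (any(A < 0) || any(A > 1 + 1e-12)) stop("adjacency must lie in [0, 1]")
  n <- nrow(A)
  k <- colSums(A) - diag(A)
  AA <- A %*% A
  # (A^2)_ij counts u = i and u = j; remove them (diag(A) = 1)
  L <- AA - A * (diag(A)[row(A)] + diag(A)[col(A)])
  denom <- outer(k, k, pmin) + 1 - A
  TOM <- (L + A) / denom
  diag(TOM) <- 1
  TOM <- pmin(pmax(TOM, 0), 1)
  dimnames(TOM) <- dimnames(A)
  TOM
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut at `cut_height` times the maximum merge height.
#' Resulting clusters smaller than `min_module_size` are relabeled grey;
#' surviving modules are colored by descending size (turquoise, blue,
#' brown, ...), ties broken by the lower smallest gene index.
#'
#' @param TOM topological overlap matrix with dimnames.
#' @param min_module_size smallest retained module (default 300, the
#'   scale of genome-wide runs; scale down for small matrices).
#' @param cut_height fraction of the maximum merge height at which the
#'   tree is cut, in (0, 1] (default 0.99).
#' @return An object of class `module_partition`: list with `gene_ids`,
#'   `module` (named color vector, `"grey"` = unassigned), `tree` (the
#'   hclust object) and `cut_height_used`.
#' @export
detect_modules <- function(TOM, min_module_size = 300, cut_height = 0.99) {
  n <- nrow(TOM)
  if (n < 2L) stop("need at least 2 genes to detect modules")
  if (cut_height <= 0 || cut_height > 1) stop("cut_height must be in (0, 1]")
  gene_ids <- rownames(TOM)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(n))
  tree <- hclust(as.dist(1 - TOM), method = "average")
  # guard against numerical dust when all profiles coincide
  h <- max(cut_height * max(tree$height), 1e-10)
  raw <- cutree(tree, h = h)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  # rank retained clusters by size, ties by first gene index
  first_idx <- vapply(big, function(cl) min(which(raw == as.integer(cl))),
                      integer(1L))
  ord <- big[order(-as.integer(sizes[big]), first_idx)]
  if (length(ord) > length(MODULE_COLORS)) {
    ord <- ord  # fall back to numbered labels past the palette
  }
  lab <- setNames(rep("grey", n), gene_ids)
  for (i in seq_along(ord)) {
    col <- if (i <= length(MODULE_COLORS)) MODULE_COLORS[i] else
      paste0("module", i)
    lab[raw == as.integer(ord[i])] <- col
  }
  structure(list(gene_ids = gene_ids, module = lab, tree = tree,
                 cut_height_used = h),
            class = "module_partition")
}

#' Assign developmental groups to modules
#'
#' Each module's mean log-normalized stage profile is summarised by its
#' peak stage; the peak's developmental group (I: pre-neurula, II:
#' tailbud, III: post-hatching; see [stage_group()]) becomes the module
#' group. Ties go to the earlier stage. The grey (unassigned) pool gets
#' no group.
#'
#' @param partition a `module_partition`.
#' @param log_matrix log-normalized genes x stages matrix covering the
#'   partitioned genes, with stage columns in canonical order.
#' @return The partition with elements `group` (module -> `"I"`/`"II"`/
#'   `"III"`), `peak_stage` (module -> stage) and `module_profile`
#'   (modules x stages mean profiles) added.
#' @export
assign_groups <- function(partition, log_matrix) {
  stopifnot(inherits(partition, "module_partition"))
  missing <- setdiff(partition$gene_ids, rownames(log_matrix))
  if (length(missing) > 0L) {
    stop("expression matrix lacks partitioned gene(s): ",
         paste(head(missing, 3L), collapse = ", "))
  }
  mods <- setdiff(unique(partition$module), "grey")
  prof <- t(vapply(mods, function(m) {
    colMeans(log_matrix[names(partition$module)[partition$module == m], ,
                        drop = FALSE])
  }, numeric(ncol(log_matrix))))
  rownames(prof) <- mods
  peak <- colnames(log_matrix)[apply(prof, 1L, which.max)]  # first max wins
  partition$peak_stage <- setNames(peak, mods)
  partition$group <- setNames(stage_group(peak), mods)
  partition$module_profile <- prof
  partition
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression
#' submatrix, exposed for diagnostics. The sign is fixed so that the
#' eigengene correlates positively with the module mean profile.
#'
#' @param partition a `module_partition`.
#' @param log_matrix log-normalized genes x stages matrix.
#' @return Matrix, modules x stages.
#' @export
module_eigengenes <- function(partition, log_matrix) {
  mods <- setdiff(unique(partition$module), "grey")
  out <- t(vapply(mods, function(m) {
    sub <- log_matrix[names(partition$module)[partition$module == m], ,
                      drop = FALSE]
    sds <- apply(sub, 1L, stats::sd)
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2L) return(colMeans(sub))
    z <- t(scale(t(sub)))
    pc <- prcomp(t(z), center = FALSE, scale. = FALSE)$x[, 1L]
    if (cor(pc, colMeans(z)) < 0) pc <- -pc
    pc
  }, numeric(ncol(log_matrix))))
  rownames(out) <- mods
  out
}

#' Cross-tabulate TF families against modules
#'
#' @param partition a `module_partition`.
#' @param assignments TF assignment table (see [classify_proteome()])
#'   covering every partitioned non-grey gene.
#' @return Integer matrix families x modules (grey excluded); row sums
#'   are per-family partitioned-gene counts, column sums module sizes.
#' @export
family_module_table <- function(partition, assignments) {
  mod <- partition$module[partition$module != "grey"]
  fam <- assignments$family[match(names(mod), assignments$gene_id)]
  if (anyNA(fam)) {
    stop("gene(s) lack a family assignment: ",
         paste(head(names(mod)[is.na(fam)], 3L), collapse = ", "))
  }
  mods_present <- intersect(c(MODULE_COLORS,
                              setdiff(unique(mod), MODULE_COLORS)),
                            unique(mod))
  tab <- table(factor(fam, levels = sort(unique(fam))),
               factor(mod, levels = mods_present))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Gene ordering for a module-structured correlation heatmap
#'
#' Orders genes by (developmental group, module size rank, within-module
#' dendrogram order), with grey genes last, and reports the block
#' boundaries at module changes.
#'
#' @param partition a `module_partition`, after [assign_groups()].
#' @param C gene-gene correlation matrix (used only to report block
#'   contrast; may be `NULL`).
#' @return List with `order` (gene ids), `block_module` (module per
#'   block), `boundaries` (cumulative end index of each block) and, when
#'   `C` is supplied, `within_block_cor` and `between_block_cor` (mean
#'   off-diagonal correlations).
#' @export
order_for_heatmap <- function(partition, C = NULL) {
  stopifnot(inherits(partition, "module_partition"))
  mod <- partition$module
  dendro_pos <- match(partition$gene_ids, partition$gene_ids[
    partition$tree$order])
  mods <- setdiff(unique(mod), "grey")
  size_rank <- rank(-vapply(mods, function(m) sum(mod == m), numeric(1L)),
                    ties.method = "first")
  names(size_rank) <- mods
  grp <- if (!is.null(partition$group)) partition$group else
    setNames(rep("I", length(mods)), mods)
  grp_ord <- c(I = 1L, II = 2L, III = 3L)[grp[mods]]
  names(grp_ord) <- mods
  key_grp <- ifelse(mod == "grey", 4L, grp_ord[mod])
  key_rank <- ifelse(mod == "grey", Inf, size_rank[mod])
  ord <- order(key_grp, key_rank, dendro_pos)
  genes <- partition$gene_ids[ord]
  mod_ordered <- mod[ord]
  change <- which(diff(as.integer(factor(mod_ordered,
                                         levels = unique(mod_ordered)))) != 0)
  boundaries <- c(change, length(genes))
  block_module <- mod_ordered[c(1L, change + 1L)]
  out <- list(order = genes, block_module = unname(block_module),
              boundaries = boundaries)
  if (!is.null(C)) {
    blk <- rep(seq_along(boundaries),
               times = diff(c(0L, boundaries)))
    Cb <- C[genes, genes]
    same <- outer(blk, blk, "==") & upper.tri(Cb)
    diff_blk <- outer(blk, blk, "!=") & upper.tri(Cb)
    out$within_block_cor <- mean(Cb[same])
    out$between_block_cor <- if (any(diff_blk)) mean(Cb[diff_blk]) else NA_real_
  }
  out
}

#' Fit a weighted co-expression network over developmental stages
#'
#' The full network pipeline as one fit: genes expressed in at least one
#' stage (FPKM strictly above `inclusion_threshold`, default 0) enter the
#' network; profiles are log10(FPKM + 1) normalized; Pearson correlation,
#' soft-threshold adjacency, topological overlap, average-linkage module
#' detection and developmental-group assignment follow. Defaults mirror
#' genome-scale practice (power 12, minimum module size 300, cut height
#' 0.99, unsigned network).
#'
#' @param expr genes x stages FPKM matrix with dimnames (stages in
#'   canonical order; see [read_expression_table()]).
#' @param power soft-threshold exponent (default 12).
#' @param min_module_size smallest retained module (default 300).
#' @param cut_height static cut as a fraction of the maximum merge
#'   height (default 0.99).
#' @param network_sign `"unsigned"` (default) or `"signed"`.
#' @param inclusion_threshold FPKM level a gene must exceed in at least
#'   one stage to enter the network (default 0).
#' @return An object of class `tf_coexpression`: list with `expr`,
#'   `log_expr`, `correlation`, `adjacency`, `tom`, `partition` (a
#'   `module_partition` with groups), `params` and `excluded` (genes
#'   never expressed).
#' @export
#' @examples
#' sim <- simulate_expression(60, module_spec = list(
#'   list(size = 30, peak_stage = "2-8cells", within_correlation = 1),
#'   list(size = 30, peak_stage = "mj", within_correlation = 1)),
#'   seed = 1)
#' fit <- tf_coexpression(sim$expr, min_module_size = 10)
#' fit
tf_coexpression <- function(expr, power = 12, min_module_size = 300,
                            cut_height = 0.99,
                            network_sign = c("unsigned", "signed"),
                            inclusion_threshold = 0) {
  network_sign <- match.arg(network_sign)
  keep <- apply(expr, 1L, function(x) any(x > inclusion_threshold))
  excluded <- rownames(expr)[!keep]
  expr_used <- expr[keep, , drop = FALSE]
  logm <- normalize_log10(expr_used)
  C <- correlation_matrix(logm)
  A <- soft_adjacency(C, power, network_sign)
  TOM <- compute_tom(A)
  part <- detect_modules(TOM, min_module_size, cut_height)
  part <- assign_groups(part, logm)
  structure(list(expr = expr_used, log_expr = logm, correlation = C,
                 adjacency = A, tom = TOM, partition = part,
                 params = list(power = power,
                               min_module_size = min_module_size,
                               cut_height = cut_height,
                               network_sign = network_sign,
                               inclusion_threshold = inclusion_threshold),
                 excluded = excluded),
            class = "tf_coexpression")
}

#' @export
print.tf_coexpression <- function(x, ...) {
  mod <- x$partition$module
  cat("Co-expression network fit\n")
  cat(sprintf("  %d genes x %d stages (power %g, %s network)\n",
              nrow(x$expr), ncol(x$expr), x$params$power,
              x$params$network_sign))
  cat(sprintf("  modules: %d (+ %d genes in grey)\n",
              length(setdiff(unique(mod), "grey")), sum(mod == "grey")))
  invisible(x)
}

#' @method summary tf_coexpression
#' @export
summary.tf_coexpression <- function(object, ...) {
  mod <- object$partition$module
  mods <- setdiff(unique(mod), "grey")
  sizes <- vapply(mods, function(m) sum(mod == m), integer(1L))
  df <- data.frame(module = mods, size = sizes,
                   group = unname(object$partition$group[mods]),
                   peak_stage = unname(object$partition$peak_stage[mods]),
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$size), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(modules = df, n_grey = sum(mod == "grey"),
                 params = object$params),
            class = "summary.tf_coexpression")
}

#' @export
print.summary.tf_coexpression <- function(x, ...) {
  cat("Modules by size:\n")
  print(x$modules)
  cat("grey (unassigned):", x$n_grey, "genes\n")
  invisible(x)
}

#' Correlation heatmap ordered by module blocks
#'
#' @param x a `tf_coexpression` fit.
#' @param ... passed to [graphics::image()].
#' @return The [order_for_heatmap()] layout, invisibly.
#' @method plot tf_coexpression
#' @export
plot.tf_coexpression <- function(x, ...) {
  lay <- order_for_heatmap(x$partition, x$correlation)
  n <- length(lay$order)
  Cb <- x$correlation[lay$order, rev(lay$order)]
  graphics::image(seq_len(n), seq_len(n), Cb, zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red 2"),
                  xlab = "", ylab = "", axes = FALSE, ...)
  graphics::abline(v = lay$boundaries + 0.5,
                   h = n - lay$boundaries + 0.5, lwd = 0.5)
  graphics::box()
  invisible(lay)
}
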