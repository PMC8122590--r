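## Hypergeometric term enrichment of a gene subset against a background,
## with Benjamini-Hochberg adjustment, and comparative-Ct (2^-ddCt)
## relative expression.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn from a
#' background of `N` genes of which `K` carry the annotation.
#'
#' @param k observed annotated genes in the target set.
#' @param K annotated genes in the background.
#' @param n target-set size.
#' @param N background size.
#' @return p-value in `[0, 1]`.
#' @export
hypergeometric_upper <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(n, K) || K > N || n > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a target gene set against a background
#'
#' One-sided hypergeometric test per annotation term present in the
#' background, Benjamini-Hochberg adjusted over all tested terms (terms
#' with zero background genes are skipped and do not count toward the
#' adjustment), ranked by p-value (ties by term id) and truncated to the
#' top `top_n`.
#'
#' @param target character vector of target gene ids; must be a subset
#'   of `background`.
#' @param background character vector of background gene ids.
#' @param annotations data frame with columns `gene_id` and `term_id`.
#' @param top_n rows to keep after ranking (default 20).
#' @return Data frame with columns `term_id`, `k`, `K`, `n`, `N`,
#'   `fold`, `p_value`, `q_value`.
#' @export
enrich <- function(target, background, annotations, top_n = 20L) {
  target <- unique(target)
  background <- unique(background)
  if (!all(target %in% background)) {
    stop("target genes must be a subset of the background")
  }
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  if (nrow(ann) == 0L) {
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), fold = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  n <- length(target)
  N <- length(background)
  K <- table(ann$term_id)
  in_target <- ann$gene_id %in% target
  k <- table(factor(ann$term_id[in_target], levels = names(K)))
  res <- data.frame(term_id = names(K),
                    k = as.integer(k), K = as.integer(K),
                    n = n, N = N, stringsAsFactors = FALSE)
  res$fold <- (res$k / n) / (res$K / N)
  res$p_value <- mapply(hypergeometric_upper, res$k, res$K,
                        MoreArgs = list(n = n, N = N))
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  head(res, top_n)
}

#' Relative expression by the comparative Ct method
#'
#' Computes `2^-ddCt` where `dCt = Ct_target - Ct_reference` within each
#' condition and `ddCt = dCt_treated - dCt_control`. Identical
#' measurements give 1; `delta_delta_ct(a, b) * delta_delta_ct(b, a)`
#' is always 1.
#'
#' @param treated,control lists (or one-row data frames) with elements
#'   `ct_target` and `ct_reference` (e.g. 18S rRNA) holding finite Ct
#'   values.
#' @return Relative expression of treated versus control.
#' @export
delta_delta_ct <- function(treated, control) {
  get_ct <- function(x, which) {
    v <- x[[which]]
    if (is.null(v) || !is.finite(v)) stop("Ct value '", which,
                                          "' missing or non-finite")
    v
  }
  d_treated <- get_ct(treated, "ct_target") - get_ct(treated, "ct_reference")
  d_control <- get_ct(control, "ct_target") - get_ct(control, "ct_reference")
  2^-(d_treated - d_control)
}
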