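# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation: plain loops
# and closed forms only.

# family assignment by exhaustive case analysis over the hit list
oracle_assign <- function(hits, rules) {
  thr <- rules$rules$evalue_threshold
  thr[is.na(thr)] <- rules$default_threshold
  names(thr) <- rules$rules$pfam_accession
  fam_of <- setNames(rules$rules$family, rules$rules$pfam_accession)
  dbd_of <- setNames(rules$rules$is_dbd, rules$rules$pfam_accession)
  pass <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    acc <- hits$pfam_accession[i]
    pass[i] <- acc %in% names(thr) && hits$full_seq_evalue[i] <= thr[acc]
  }
  ph <- hits[pass, , drop = FALSE]
  if (nrow(ph) == 0L) return(NULL)
  fams <- unname(fam_of[ph$pfam_accession])
  is_dbd <- unname(dbd_of[ph$pfam_accession]) == 1L
  if (!any(is_dbd)) return(NULL)
  # compound rules first
  for (i in seq_len(nrow(rules$compound_rules))) {
    req <- rules$compound_rules$required[[i]]
    if (all(req %in% fams)) {
      return(list(family = rules$compound_rules$host_family[i],
                  subtype = rules$compound_rules$subtype[i],
                  candidates = sort(unique(fams[is_dbd]))))
    }
  }
  # min e-value, then max bit score, then alphabetical family
  best <- NULL
  for (i in which(is_dbd)) {
    cand <- list(e = ph$full_seq_evalue[i], b = ph$bit_score[i],
                 f = fams[i])
    if (is.null(best) ||
        cand$e < best$e ||
        (cand$e == best$e && cand$b > best$b) ||
        (cand$e == best$e && cand$b == best$b && cand$f < best$f)) {
      best <- cand
    }
  }
  list(family = best$f, subtype = NA_character_,
       candidates = sort(unique(fams[is_dbd])))
}

# topological overlap by a literal double loop
oracle_tom <- function(A) {
  n <- nrow(A)
  TOM <- diag(n)
  for (i in seq_len(n)) {
    k_i <- sum(A[i, -i])
    for (j in seq_len(n)) {
      if (i == j) next
      k_j <- sum(A[j, -j])
      l_ij <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l_ij <- l_ij + A[i, u] * A[u, j]
      }
      TOM[i, j] <- (l_ij + A[i, j]) / (min(k_i, k_j) + 1 - A[i, j])
    }
  }
  TOM
}

# Kendall tau-b by O(n^2) concordant/discordant pair counting
oracle_tau <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) C <- C + 1
      else D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((C + D + tx) * (C + D + ty))
  if (denom == 0) return(0)
  (C - D) / denom
}

# hypergeometric upper tail by explicit pmf summation over the support
oracle_hyper_upper <- function(k, K, n, N) {
  lo <- max(0, n - (N - K))
  hi <- min(n, K)
  pmf <- function(x) exp(lchoose(K, x) + lchoose(N - K, n - x) -
                           lchoose(N, n))
  if (k > hi) return(0)
  sum(vapply(max(k, lo):hi, pmf, numeric(1L)))
}

# Benjamini-Hochberg step-up applied by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# random small domain-hit table over the default rule set
random_hits <- function(n, rules, protein = "gene1.p1") {
  acc <- sample(rules$rules$pfam_accession, n, replace = TRUE)
  data.frame(protein_id = protein, pfam_accession = acc,
             domain_name = acc,
             full_seq_evalue = 10^runif(n, -12, 0),
             ind_domain_evalue = 10^runif(n, -12, 0),
             bit_score = round(runif(n, 10, 200), 1),
             env_start = 1L, env_end = 50L,
             stringsAsFactors = FALSE)
}
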