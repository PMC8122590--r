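make_hit <- function(acc, e, protein = "g1.p1", score = 50, name = acc) {
  data.frame(protein_id = protein, pfam_accession = acc, domain_name = name,
             full_seq_evalue = e, ind_domain_evalue = e, bit_score = score,
             env_start = 1L, env_end = 50L, stringsAsFactors = FALSE)
}

test_that("per-family thresholds screen hits with an inclusive boundary", {
  rules <- default_family_rules()
  hits <- rbind(
    make_hit("PF00096", 5e-4),   # zf-C2H2, family threshold 1e-3: retained
    make_hit("PF00010", 5e-3),   # bHLH, threshold 1e-2: retained
    make_hit("PF00178", 5e-3),   # Ets, default 1e-4: dropped
    make_hit("PF00178", 1e-4),   # exactly at threshold: retained
    make_hit("PF99999", 1e-30)   # unknown accession: dropped silently
  )
  out <- apply_thresholds(hits, rules)
  expect_equal(out$pfam_accession, c("PF00096", "PF00010", "PF00178"))
  expect_equal(out$family, c("zf-C2H2", "bHLH", "Ets"))
})

test_that("the independent-domain e-value can be screened instead", {
  rules <- default_family_rules()
  h <- make_hit("PF00178", 1)          # full-sequence e-value fails
  h$ind_domain_evalue <- 1e-6          # per-domain e-value passes
  expect_equal(nrow(apply_thresholds(h, rules)), 0L)
  expect_equal(nrow(apply_thresholds(h, rules, "ind_domain")), 1L)
})

test_that("compound BTB + zf-C2H2 architectures are classified as ZBTB", {
  rules <- default_family_rules()
  hits <- apply_thresholds(rbind(make_hit("PF00651", 1e-6),
                                 make_hit("PF00096", 1e-5)), rules)
  a <- assign_family("g1", hits, rules)
  expect_equal(a$family, "zf-C2H2")
  expect_equal(a$subtype, "ZBTB")
  expect_equal(a$superfamily, "zinc finger")

  # a lone passing homeodomain is just a homeodomain TF
  hits <- apply_thresholds(make_hit("PF00046", 1e-8), rules)
  a <- assign_family("g2", hits, rules)
  expect_equal(a$family, "Homeodomain")
  expect_true(is.na(a$subtype))

  # a lone passing BTB (no DBD) does not make the gene a TF
  hits <- apply_thresholds(make_hit("PF00651", 1e-9), rules)
  expect_null(assign_family("g3", hits, rules))
})

test_that("multi-family genes resolve by smallest e-value with an audit trail", {
  rules <- default_family_rules()
  hits <- apply_thresholds(rbind(make_hit("PF00096", 1e-6),
                                 make_hit("PF00046", 1e-5)), rules)
  a <- assign_family("g1", hits, rules)
  expect_equal(a$family, "zf-C2H2")
  expect_setequal(a$candidate_families[[1]], c("zf-C2H2", "Homeodomain"))

  # hits spanning genes are a contract violation
  hits$gene_id <- c("g1", "g2")
  expect_error(assign_family("g1", hits, rules), "multiple gene_ids")
})

test_that("family assignment agrees with exhaustive case enumeration", {
  rules <- default_family_rules()
  set.seed(101)
  for (i in 1:40) {
    hits <- random_hits(sample(1:20, 1), rules)
    expected <- oracle_assign(hits, rules)
    got <- assign_family("gene1", apply_thresholds(hits, rules), rules)
    if (is.null(expected)) {
      expect_null(got)
    } else {
      expect_equal(got$family, expected$family, info = paste("case", i))
      expect_equal(is.na(got$subtype), is.na(expected$subtype))
      expect_equal(got$candidate_families[[1]], expected$candidates)
    }
  }
})

test_that("tightening a family threshold never increases assigned TFs", {
  rules <- default_family_rules()
  set.seed(7)
  sim <- simulate_domtblout(n_tf = 60, n_decoys = 30, n_compound = 6,
                            seed = 17)
  n_assigned <- function(r) nrow(classify_proteome(sim$hits, sim$proteins, r))
  base <- n_assigned(rules)
  for (tighter in c(1e-5, 1e-8, 1e-12)) {
    r2 <- rules
    r2$rules$evalue_threshold <- pmin(
      ifelse(is.na(r2$rules$evalue_threshold), r2$default_threshold,
             r2$rules$evalue_threshold), tighter)
    r2$default_threshold <- min(r2$default_threshold, tighter)
    n2 <- n_assigned(r2)
    expect_lte(n2, base)
    base <- n2
  }
})

test_that("proteome classification recovers planted families exactly", {
  sim <- simulate_domtblout(n_tf = 120, n_decoys = 80, n_compound = 12,
                            seed = 7)
  a <- classify_proteome(sim$hits, sim$proteins)
  truth <- sim$truth[sim$truth$role == "tf", ]
  expect_equal(nrow(a), 120L)
  expect_setequal(a$gene_id, truth$gene_id)
  expect_equal(a$family[match(truth$gene_id, a$gene_id)], truth$family)
  expect_equal(count_subtype(a, "ZBTB"), 12L)
  # no decoy is ever assigned
  expect_equal(sum(grepl("^decoy", a$gene_id)), 0L)
  # partition: one assignment per gene
  expect_equal(anyDuplicated(a$gene_id), 0L)
  expect_equal(sum(table(a$family)), nrow(a))
})

test_that("edge cases: empty hits, absent subtypes, unknown proteins", {
  rules <- default_family_rules()
  prot <- data.frame(protein_id = "g1.p1", gene_id = "g1",
                     sequence_length = 100L)
  expect_equal(nrow(classify_proteome(empty_hits <- make_hit("PF00096",
                                                             1)[0, ],
                                      prot, rules)), 0L)
  a <- classify_proteome(make_hit("PF00046", 1e-8, protein = "g1.p1"),
                         prot, rules)
  expect_equal(count_subtype(a, "ZBTB"), 0L)
  expect_equal(count_subtype(a, "NOT_A_SUBTYPE"), 0L)
  expect_error(classify_proteome(make_hit("PF00046", 1e-8,
                                          protein = "missing.p1"),
                                 prot, rules), "absent from the proteome")
})
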