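# an 8-gene Hox-like cluster where only the hox2..hox4 window is
# strictly reverse-ordered (onsets: tb, gast, 2-8cells), mirroring the
# published subcluster pattern; hox5 lacks an onset and breaks windows
fig_cluster <- function() {
  data.frame(
    gene_id = c("hox1", "hox2", "hox3", "hox4", "hox5", "hox10", "hox12",
                "hox13"),
    onset = c("tb", "tb", "gast", "2-8cells", NA, "tb", "neu", "tb"),
    stringsAsFactors = FALSE)
}

test_that("chromosome census reports single-chromosome clusters", {
  loci8 <- data.frame(gene_id = paste0("hox", 1:8), chromosome = "chr3",
                      start = (0:7) * 1000, end = (0:7) * 1000 + 500,
                      strand = "+")
  cc <- chromosome_census(loci8)
  expect_true(cc$single_chromosome)
  expect_equal(unname(cc$counts), 8L)

  split2 <- loci8
  split2$chromosome[5:8] <- "chr7"
  expect_false(chromosome_census(split2)$single_chromosome)

  set.seed(5)
  chroms <- sample(paste0("chr", 1:16), 132, replace = TRUE)
  loci <- data.frame(gene_id = paste0("z", 1:132), chromosome = chroms,
                     start = 0, end = 100, strand = ".")
  cc <- chromosome_census(loci)
  expect_equal(cc$counts[names(table(chroms))],
               setNames(as.integer(table(chroms)), names(table(chroms))))
})

test_that("onset is the earliest stage strictly above the threshold", {
  m <- rbind(tb_only = c(0, 0, 0, 50, 0, 0, 0),
             silent = rep(0, 7),
             always = rep(99, 7),
             late = c(0, 0, 0, 0, 12, 30, 40))
  colnames(m) <- dev_stages()
  expect_equal(onset_stage(m, "tb_only"), "tb")
  expect_true(is.na(onset_stage(m, "silent")))
  expect_equal(onset_stage(m, "always"), "2-8cells")
  expect_equal(onset_stage(m, "late"), "hsl")
  expect_equal(onset_stage(m, "late", threshold = 20), "trl")
  expect_error(onset_stage(m, "nope"), "unknown gene")
  expect_equal(unname(onset_stages(m)), c("tb", NA, "2-8cells", "hsl"))
})

test_that("Kendall tau matches O(n^2) pair counting and handles ties", {
  # the reverse-collinear published subcluster: onsets tb, gast, 2-8cells
  r <- match(c("tb", "gast", "2-8cells"), dev_stages())
  expect_equal(collinearity_tau(1:3, r), -1)
  # identical onsets for all genes: tau undefined -> 0
  expect_equal(collinearity_tau(1:4, rep(2, 4)), 0)
  set.seed(77)
  for (i in 1:30) {
    x <- seq_len(5)
    y <- sample(1:4, 5, replace = TRUE)
    expect_equal(collinearity_tau(x, y), oracle_tau(x, y),
                 tolerance = 1e-12, info = paste(y, collapse = ","))
  }
  expect_error(collinearity_tau(1:2, 1:2), "at least 3")
  expect_error(collinearity_tau(1:3, c(1, NA, 2)), "missing onset")
})

test_that("maximal collinear windows are found by exhaustive comparison", {
  res <- find_collinear_subclusters(fig_cluster())
  expect_equal(nrow(res), 1L)
  expect_equal(res$orientation, "reverse")
  expect_equal(res$genes[[1]], c("hox2", "hox3", "hox4"))
  expect_equal(res$tau, -1)

  # a fully forward cluster reports one maximal window, no sub-windows
  fwd <- data.frame(gene_id = paste0("g", 1:5),
                    onset = dev_stages()[1:5])
  res <- find_collinear_subclusters(fwd)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start, 1L)
  expect_equal(res$end, 5L)
  expect_equal(res$orientation, "forward")

  # all onsets equal: no perfect window
  flat <- data.frame(gene_id = paste0("g", 1:5), onset = rep("tb", 5))
  expect_equal(nrow(find_collinear_subclusters(flat)), 0L)

  # every reported window re-evaluates to |tau| = 1 and cannot extend
  set.seed(13)
  for (i in 1:20) {
    cl <- data.frame(gene_id = paste0("g", 1:8),
                     onset = sample(c(dev_stages(), NA), 8, replace = TRUE))
    res <- find_collinear_subclusters(cl)
    for (w in seq_len(nrow(res))) {
      idx <- res$start[w]:res$end[w]
      expect_false(anyNA(cl$onset[idx]))
      expect_equal(abs(oracle_tau(idx, match(cl$onset[idx], dev_stages()))),
                   1, tolerance = 1e-12)
    }
  }
})

test_that("reversing genomic order flips orientations and negates tau", {
  cl <- fig_cluster()
  fwd <- find_collinear_subclusters(cl)
  rev_cl <- cl[rev(seq_len(nrow(cl))), ]
  bwd <- find_collinear_subclusters(rev_cl)
  expect_equal(nrow(bwd), nrow(fwd))
  expect_equal(sort(unlist(bwd$genes)), sort(unlist(fwd$genes)))
  expect_equal(bwd$tau, -fwd$tau)
  expect_equal(bwd$orientation, "forward")
})

test_that("cluster arrangements compare order and linkage", {
  a <- data.frame(pg = c(1, 2, 3, 4, 5, 10, 12, 13), chromosome = "chr1")
  expect_identical(compare_arrangements(a, a),
                   list(shared_pgs = a$pg, same_order = TRUE,
                        same_linkage = TRUE))
  # reversal of the shared groups still counts as the same arrangement
  b <- data.frame(pg = rev(a$pg), chromosome = "chrX")
  expect_true(compare_arrangements(a, b)$same_order)

  split2 <- data.frame(pg = c(1, 2, 3, 4, 5, 10, 12, 13),
                       chromosome = rep(c("chr1", "chr2"), each = 4))
  expect_false(compare_arrangements(a, split2)$same_linkage)

  # scrambled shared groups: verified against a direct order comparison
  set.seed(3)
  for (i in 1:10) {
    sc <- data.frame(pg = sample(a$pg), chromosome = "chr1")
    got <- compare_arrangements(a, sc)$same_order
    shared <- intersect(a$pg, sc$pg)
    av <- a$pg[a$pg %in% shared]
    bv <- sc$pg[sc$pg %in% shared]
    expect_equal(got, identical(av, bv) || identical(av, rev(bv)))
  }
})
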