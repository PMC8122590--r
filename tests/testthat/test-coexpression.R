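test_that("log10(FPKM + 1) normalization and its inverse", {
  expect_equal(normalize_log10(matrix(0)), matrix(0))
  expect_equal(normalize_log10(matrix(c(9, 99), 1)), matrix(c(1, 2), 1))
  set.seed(4)
  m <- matrix(runif(70, 0, 1000), 10, 7)
  expect_equal(10^normalize_log10(m) - 1, m, tolerance = 1e-12)
  expect_error(normalize_log10(matrix(-1)), "non-negative")
})

test_that("expressed calls use a strict FPKM threshold", {
  sim <- simulate_expression(200, module_spec = list(
    list(size = 80, peak_stage = "2-8cells", within_correlation = 0.95)),
    seed = 21)
  expressed <- call_expressed(sim$expr, "2-8cells", threshold = 10)
  # planted early-peaked genes reach FPKM 10^2.2 - 1 at their peak
  planted <- sim$truth$gene_id[sim$truth$module == 1]
  expect_true(all(planted %in% expressed))
  expect_equal(expressed_proportion(sim$expr, "2-8cells", 200),
               round(100 * length(expressed) / 200, 2))
  expect_length(call_expressed(sim$expr, "2-8cells", threshold = Inf), 0L)
  expect_error(call_expressed(sim$expr, "adult"), "unknown stage")
  # the printed maternal proportion arithmetic: 290 of 553
  toy <- matrix(0, 553, 7, dimnames = list(sprintf("g%03d", 1:553),
                                           dev_stages()))
  toy[1:290, "2-8cells"] <- 50
  expect_equal(expressed_proportion(toy, "2-8cells", 553), 52.44)
})

test_that("gene-gene correlation matches a brute-force computation", {
  set.seed(8)
  m <- matrix(runif(140), 20, 7,
              dimnames = list(paste0("g", 1:20), dev_stages()))
  C <- correlation_matrix(m)
  expect_equal(diag(C), setNames(rep(1, 20), rownames(m)))
  expect_equal(C, t(C))
  brute <- matrix(1, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    xi <- m[i, ] - mean(m[i, ]); xj <- m[j, ] - mean(m[j, ])
    brute[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_equal(matrix(C, 20, 20), brute, tolerance = 1e-12)

  # proportional profiles correlate at 1, mirrored profiles at -1
  x <- c(1, 3, 2, 5, 4, 6, 7)
  two <- rbind(a = x, b = 2 * x, c = mean(x) - (x - mean(x)))
  colnames(two) <- dev_stages()
  C2 <- correlation_matrix(two)
  expect_equal(C2["a", "b"], 1)
  expect_equal(C2["a", "c"], -1)

  # zero-variance genes are flagged and decorrelated
  flat <- rbind(two, d = rep(1, 7))
  Cf <- correlation_matrix(flat)
  expect_equal(attr(Cf, "zero_variance"), "d")
  expect_equal(unname(Cf["d", c("a", "b", "c")]), c(0, 0, 0))
  expect_equal(Cf["d", "d"], 1)
  expect_error(correlation_matrix(m[, 1:2]), "at least 3")
})

test_that("correlation is invariant to affine rescaling of a log profile", {
  set.seed(12)
  m <- matrix(runif(35), 5, 7)
  m2 <- m
  m2[3, ] <- 2.5 * m[3, ] + 7
  expect_equal(correlation_matrix(m), correlation_matrix(m2),
               tolerance = 1e-12)
})

test_that("soft adjacency follows its closed form and is monotone", {
  C <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(soft_adjacency(C, 12)[1, 2], 0.5^12)
  expect_equal(soft_adjacency(matrix(1, 2, 2), 7)[1, 2], 1)
  expect_equal(soft_adjacency(C, 12, "signed")[1, 2], 0.75^12)
  grid <- seq(-1, 1, by = 0.05)
  a <- vapply(grid, function(c) soft_adjacency(matrix(c(1, c, c, 1), 2),
                                               12)[1, 2], numeric(1))
  expect_true(all(diff(a[grid >= 0]) >= 0))    # nondecreasing in |c|
  expect_equal(rev(a[grid < 0]), a[grid > 0])  # symmetric in the sign
  expect_error(soft_adjacency(C, 0.5), ">= 1")
})

test_that("topological overlap equals an independent double-loop evaluation", {
  set.seed(30)
  for (i in 1:3) {
    C <- correlation_matrix(matrix(runif(210), 30, 7))
    A <- soft_adjacency(C, 6)
    TOM <- compute_tom(A)
    expect_equal(unname(TOM), oracle_tom(unname(A)), tolerance = 1e-10)
    expect_true(all(TOM >= 0 & TOM <= 1))
    expect_equal(TOM, t(TOM))
  }
  # closed forms: complete overlap and no overlap
  expect_true(all(compute_tom(matrix(1, 4, 4)) == 1))
  expect_true(all(compute_tom(diag(4))[upper.tri(diag(4))] == 0))
  # two genes, a_12 = 0.5: TOM = (0 + 0.5)/(0.5 + 1 - 0.5) = 0.5
  A2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(compute_tom(A2)[1, 2], 0.5)
  expect_equal(compute_tom(A2)[1, 2], oracle_tom(A2)[1, 2])
})

test_that("noiseless planted modules are recovered exactly", {
  sim <- simulate_expression(150, module_spec = list(
    list(size = 50, peak_stage = "2-8cells", within_correlation = 1),
    list(size = 50, peak_stage = "tb", within_correlation = 1),
    list(size = 50, peak_stage = "mj", within_correlation = 1)), seed = 1)
  fit <- tf_coexpression(sim$expr, min_module_size = 20)
  mods <- setdiff(unique(fit$partition$module), "grey")
  expect_length(mods, 3L)
  expect_equal(ari(fit$partition$module, sim$truth$module), 1)
  # size-ranked colors: equal sizes resolve by first-gene order
  expect_setequal(mods, c("turquoise", "blue", "brown"))
  # developmental groups from the peak stages
  expect_equal(unname(fit$partition$group[c("turquoise", "blue", "brown")]),
               c("I", "II", "III"))
})

test_that("degenerate partitions behave: one module, all grey, tiny input", {
  m <- matrix(rep(c(1, 5, 2, 8, 3, 9, 4), each = 20), 20, 7, byrow = FALSE,
              dimnames = list(paste0("g", 1:20), dev_stages()))
  part <- detect_modules(compute_tom(soft_adjacency(correlation_matrix(m),
                                                    6)),
                         min_module_size = 5)
  expect_equal(unname(part$module), rep("turquoise", 20))

  bg <- simulate_expression(60, module_spec = list(), seed = 2)
  fit <- tf_coexpression(bg$expr, min_module_size = 30)
  expect_true(all(fit$partition$module == "grey"))

  expect_error(detect_modules(matrix(1, 1, 1)), "at least 2")
  expect_error(detect_modules(matrix(1, 3, 3), cut_height = 0), "cut_height")
})

test_that("group assignment follows the peak stage with early tie-break", {
  part <- structure(list(gene_ids = c("a", "b", "c"),
                         module = setNames(c("turquoise", "turquoise",
                                             "blue"), c("a", "b", "c")),
                         tree = NULL, cut_height_used = 0),
                    class = "module_partition")
  logm <- rbind(a = c(0, 0, 0, 2, 0, 0, 0),
                b = c(0, 0, 0, 2, 0, 0, 0),
                c = rep(1, 7))
  colnames(logm) <- dev_stages()
  part <- assign_groups(part, logm)
  expect_equal(unname(part$group["turquoise"]), "II")  # peaks at tb
  expect_equal(unname(part$peak_stage["blue"]), "2-8cells")  # flat -> earliest
  expect_equal(unname(part$group["blue"]), "I")
})

test_that("family-module tables cross-tabulate exactly", {
  sim <- simulate_expression(120, module_spec = list(
    list(size = 60, peak_stage = "gast", within_correlation = 1),
    list(size = 60, peak_stage = "hsl", within_correlation = 1)), seed = 6)
  fit <- tf_coexpression(sim$expr, min_module_size = 10)
  set.seed(60)
  fams <- sample(c("zf-C2H2", "Homeodomain", "bHLH"), 120, replace = TRUE)
  assignments <- data.frame(gene_id = sim$truth$gene_id, family = fams)
  tab <- family_module_table(fit$partition, assignments)
  brute <- table(fams, fit$partition$module[sim$truth$gene_id])
  for (f in rownames(tab)) for (m in colnames(tab)) {
    expect_equal(tab[f, m], unname(brute[f, m]))
  }
  expect_equal(unname(colSums(tab)),
               unname(as.integer(table(fit$partition$module)[colnames(tab)])))
  expect_error(family_module_table(fit$partition, assignments[1:10, ]),
               "lack a family")
})

test_that("heatmap ordering forms contrasting module blocks", {
  sim <- simulate_expression(80, module_spec = list(
    list(size = 40, peak_stage = "neu", within_correlation = 1),
    list(size = 40, peak_stage = "trl", within_correlation = 1)), seed = 14)
  fit <- tf_coexpression(sim$expr, min_module_size = 10)
  lay <- order_for_heatmap(fit$partition, fit$correlation)
  expect_length(lay$boundaries, 2L)
  expect_gt(lay$within_block_cor, lay$between_block_cor)
  expect_setequal(lay$order, rownames(sim$expr))

  # single module -> one block over all genes
  one <- simulate_expression(30, module_spec = list(
    list(size = 30, peak_stage = "tb", within_correlation = 1)), seed = 15)
  fit1 <- tf_coexpression(one$expr, min_module_size = 10)
  lay1 <- order_for_heatmap(fit1$partition)
  expect_equal(lay1$boundaries, 30L)

  # shuffling the input gene order yields the same blocks
  perm <- sample(nrow(sim$expr))
  fit2 <- tf_coexpression(sim$expr[perm, ], min_module_size = 10)
  lay2 <- order_for_heatmap(fit2$partition, fit2$correlation)
  expect_equal(lengths(list(lay$boundaries, lay2$boundaries))[1],
               lengths(list(lay$boundaries, lay2$boundaries))[2])
  expect_equal(sort(lay$order[1:lay$boundaries[1]]),
               sort(lay2$order[1:lay2$boundaries[1]]))
})

test_that("the fit object prints, summarises and exposes eigengenes", {
  sim <- simulate_expression(60, module_spec = list(
    list(size = 30, peak_stage = "gast", within_correlation = 0.95),
    list(size = 30, peak_stage = "mj", within_correlation = 0.95)),
    seed = 19)
  fit <- tf_coexpression(sim$expr, min_module_size = 10)
  expect_output(print(fit), "Co-expression network fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.tf_coexpression")
  expect_equal(sum(s$modules$size) + s$n_grey, 60L)
  eg <- module_eigengenes(fit$partition, fit$log_expr)
  expect_equal(ncol(eg), 7L)
  # eigengene tracks the module mean profile
  for (m in rownames(eg)) {
    expect_gt(cor(eg[m, ], fit$partition$module_profile[m, ]), 0.9)
  }
})
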