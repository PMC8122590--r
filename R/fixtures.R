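#' Packaged reference tables from the published S. clava TF survey
#'
#' Loads the two study tables shipped with the package as plain-text
#' fixtures:
#' \describe{
#'   \item{`table1`}{TF counts per family (76 rows) for nine species:
#'     *S. clava*, *C. robusta*, *M. oculata*, *O. dioica*, *B. leachii*,
#'     *B. schlosseri*, *H. sapiens*, *B. floridae* and *C. elegans*.
#'     Superfamily membership is attached as attribute `superfamily`
#'     (named character vector, `NA` where a family belongs to none).}
#'   \item{`table2`}{TF counts per family in the nine co-expression
#'     modules (turquoise, blue, magenta, pink, brown, yellow, red,
#'     green, black), as printed.}
#' }
#' Cells are stored exactly as printed. One printed row (PBC) has module
#' entries that do not add up to its printed row total; such rows are
#' reported in `table2_inconsistent` rather than corrected.
#'
#' @return A list with elements `table1` (76 x 9 integer matrix),
#'   `table2` (61 x 9 integer matrix), `table2_printed_total` (named
#'   integer vector of the printed row totals) and `table2_inconsistent`
#'   (character vector of family rows whose printed cells disagree with
#'   their printed total).
#' @export
#' @examples
#' pt <- load_paper_tables()
#' colSums(pt$table1)          # printed "Total TFs" row
#' colSums(pt$table1 > 0)      # printed "Total TF families" row
load_paper_tables <- function() {
  p1 <- system.file("extdata", "table1_tf_counts.tsv", package = "tfcensus",
                    mustWork = TRUE)
  p2 <- system.file("extdata", "table2_module_counts.tsv",
                    package = "tfcensus", mustWork = TRUE)
  t1 <- read.delim(p1, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  t2 <- read.delim(p2, check.names = FALSE, stringsAsFactors = FALSE)

  m1 <- as.matrix(t1[, -(1:2)])
  storage.mode(m1) <- "integer"
  rownames(m1) <- t1$family
  colnames(m1) <- sub("_", ". ", colnames(m1))  # "S_clava" -> "S. clava"
  if (any(m1 < 0)) stop("fixture corrupt: negative count in table1")
  attr(m1, "superfamily") <- setNames(t1$superfamily, t1$family)

  mod_cols <- setdiff(colnames(t2), c("family", "printed_total"))
  m2 <- as.matrix(t2[, mod_cols])
  storage.mode(m2) <- "integer"
  rownames(m2) <- t2$family
  if (any(m2 < 0)) stop("fixture corrupt: negative count in table2")
  printed <- setNames(as.integer(t2$printed_total), t2$family)

  list(table1 = m1,
       table2 = m2,
       table2_printed_total = printed,
       table2_inconsistent = rownames(m2)[rowSums(m2) != printed])
}
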