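## Multi-species family count matrices and comparative set algebra:
## shared families, exclusive-shared sets, expansions, fractions, orphans.
## "Presence" of a family in a species always means count > 0.

#' Build a families-by-species TF count matrix
#'
#' @param assignments_per_species named list mapping species name to a TF
#'   assignment table (see [classify_proteome()]).
#' @param rules optional `family_rules` object; when supplied, families
#'   present in the rule set but assigned nowhere are retained as
#'   all-zero rows (so that rule families may legitimately end up with
#'   zero members).
#' @return Integer matrix, families x species. Row order: rule-set
#'   family order when `rules` is given, else alphabetical.
#' @export
build_count_matrix <- function(assignments_per_species, rules = NULL) {
  species <- names(assignments_per_species)
  if (is.null(species) && length(assignments_per_species) > 0L) {
    stop("assignments_per_species must be a named list")
  }
  fams <- sort(unique(unlist(lapply(assignments_per_species,
                                    function(a) a$family))))
  if (!is.null(rules)) fams <- union(dbd_families(rules), fams)
  m <- matrix(0L, nrow = length(fams), ncol = length(species),
              dimnames = list(fams, species))
  for (s in species) {
    tab <- table(assignments_per_species[[s]]$family)
    m[names(tab), s] <- as.integer(tab)
  }
  m
}

check_species <- function(matrix, species) {
  bad <- setdiff(species, colnames(matrix))
  if (length(bad) > 0L) {
    stop("unknown species: ", paste(bad, collapse = ", "))
  }
}

check_family <- function(matrix, family) {
  if (!family %in% rownames(matrix)) stop("unknown family: ", family)
}

#' Total TFs and total TF families of a species
#'
#' `total_tfs()` is the species' column sum; `total_families()` counts
#' families with at least one member.
#'
#' @param matrix families x species count matrix.
#' @param species a species (column) name.
#' @return Integer.
#' @export
total_tfs <- function(matrix, species) {
  check_species(matrix, species)
  sum(matrix[, species])
}

#' @rdname total_tfs
#' @export
total_families <- function(matrix, species) {
  check_species(matrix, species)
  sum(matrix[, species] > 0L)
}

#' Families shared by every species of a subset
#'
#' @param matrix families x species count matrix.
#' @param species_subset non-empty character vector of species.
#' @return Character vector of family names present (count > 0) in every
#'   listed species.
#' @export
shared_families <- function(matrix, species_subset) {
  if (length(species_subset) == 0L) stop("species subset must be non-empty")
  check_species(matrix, species_subset)
  pres <- matrix[, species_subset, drop = FALSE] > 0L
  rownames(matrix)[rowSums(pres) == length(species_subset)]
}

#' Families shared within, and exclusive to, two species groups
#'
#' Computes the families shared by every member of group A and of group
#' B, their intersection, and the two exclusive-shared sets (shared
#' throughout one group but not throughout the other).
#'
#' @param matrix families x species count matrix.
#' @param group_a,group_b non-empty character vectors of species.
#' @return List with character-vector elements `common`, `only_a`,
#'   `only_b`.
#' @export
exclusive_shared <- function(matrix, group_a, group_b) {
  a <- shared_families(matrix, group_a)
  b <- shared_families(matrix, group_b)
  list(common = intersect(a, b),
       only_a = setdiff(a, b),
       only_b = setdiff(b, a))
}

#' Family expansion between two species
#'
#' Raw count difference `count(family, a) - count(family, b)`; negative
#' values indicate contraction in species `a` relative to `b`.
#'
#' @param matrix families x species count matrix.
#' @param family family name.
#' @param species_a,species_b species names.
#' @return Integer (possibly negative).
#' @export
family_expansion <- function(matrix, family, species_a, species_b) {
  check_family(matrix, family)
  check_species(matrix, c(species_a, species_b))
  matrix[family, species_a] - matrix[family, species_b]
}

#' Percentage of a species' TFs belonging to one family
#'
#' @param matrix families x species count matrix.
#' @param family family name.
#' @param species species name; its total TF count must be positive.
#' @param digits decimals to round the reported percentage to
#'   (default 2, as conventionally printed).
#' @return Numeric percentage in `[0, 100]`.
#' @export
family_fraction <- function(matrix, family, species, digits = 2L) {
  check_family(matrix, family)
  tot <- total_tfs(matrix, species)
  if (tot == 0L) stop("family fraction undefined: species '", species,
                      "' has zero TFs")
  round(100 * matrix[family, species] / tot, digits)
}

#' Species with the largest and smallest family count in a subset
#'
#' @param matrix families x species count matrix.
#' @param family family name.
#' @param species_subset non-empty character vector of species.
#' @return List with character-vector elements `argmax` and `argmin`
#'   (sets, so ties are exposed).
#' @export
extremal_family_species <- function(matrix, family, species_subset) {
  if (length(species_subset) == 0L) stop("species subset must be non-empty")
  check_family(matrix, family)
  check_species(matrix, species_subset)
  x <- matrix[family, species_subset]
  list(argmax = names(x)[x == max(x)],
       argmin = names(x)[x == min(x)])
}

#' Orphan families of a species
#'
#' Families represented by exactly one gene in the given species.
#'
#' @param matrix families x species count matrix.
#' @param species species name.
#' @return Character vector of family names.
#' @export
orphan_families <- function(matrix, species) {
  check_species(matrix, species)
  rownames(matrix)[matrix[, species] == 1L]
}

#' Disjoint Venn regions of family presence across species
#'
#' Partitions the union of present families across a species subset into
#' the `2^k - 1` disjoint presence/absence regions.
#'
#' @param matrix families x species count matrix.
#' @param species_subset non-empty character vector of species (`k` of
#'   them).
#' @return Named list of character vectors; names encode membership as
#'   species names joined by `&`.
#' @export
venn_regions <- function(matrix, species_subset) {
  if (length(species_subset) == 0L) stop("species subset must be non-empty")
  check_species(matrix, species_subset)
  pres <- matrix[, species_subset, drop = FALSE] > 0L
  key <- apply(pres, 1L, function(r) paste(species_subset[r], collapse = "&"))
  inunion <- key != ""
  split(rownames(matrix)[inunion], key[inunion])
}
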