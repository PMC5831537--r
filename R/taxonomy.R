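# Host lineages and rank-level agreement between predicted and true hosts.

TAX_RANKS <- c("species", "genus", "family", "order", "class", "phylum")

#' Read a lineage table
#'
#' Loads a flat TSV mapping each taxon to its names at the six ranks used for
#' scoring predictions (species, genus, family, order, class, phylum). Empty
#' cells mean the rank is unknown for that taxon. Using a flat table rather
#' than live taxonomy queries keeps the benchmark self-contained.
#'
#' @param path TSV file with header
#'   `taxon, species, genus, family, order, class, phylum`.
#' @return Tibble with those seven character columns; empty cells become `NA`.
#' @export
read_lineage_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  expected <- c("taxon", TAX_RANKS)
  if (!identical(names(tbl), expected)) {
    abort(sprintf(
      "lineage table header must be '%s', got '%s'",
      paste(expected, collapse = ", "), paste(names(tbl), collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl$taxon)) abort("duplicate taxon rows in lineage table")
  tbl <- mutate(tbl, across(dplyr::everything(), ~ dplyr::na_if(.x, "")))
  tbl
}

# lineage row (1-row tibble or NULL) for a taxon name
lineage_of <- function(lineages, taxon) {
  i <- match(taxon, lineages$taxon)
  if (is.na(i)) abort(sprintf("taxon '%s' not in lineage table", taxon))
  lineages[i, ]
}

#' Ranks at which two lineages agree
#'
#' A rank is shared when both lineages carry a name at that rank and the
#' names are equal (case-insensitive exact match; no synonym resolution).
#'
#' @param lineages A lineage tibble from [read_lineage_table()].
#' @param taxon_a,taxon_b Taxon names present in `lineages`.
#' @return Character vector, a subset of
#'   `c("species","genus","family","order","class","phylum")`.
#' @export
ranks_shared <- function(lineages, taxon_a, taxon_b) {
  a <- lineage_of(lineages, taxon_a)
  b <- lineage_of(lineages, taxon_b)
  shared <- vapply(TAX_RANKS, function(r) {
    x <- a[[r]]; y <- b[[r]]
    !is.na(x) && !is.na(y) && tolower(x) == tolower(y)
  }, logical(1))
  TAX_RANKS[shared]
}

# TRUE when the lineage table is tree-consistent: equal names at a lower rank
# imply equal names at every higher rank where both are present
lineages_tree_consistent <- function(lineages) {
  for (i in seq_along(TAX_RANKS)[-length(TAX_RANKS)]) {
    lo <- lineages[[TAX_RANKS[i]]]
    for (j in (i + 1):length(TAX_RANKS)) {
      hi <- lineages[[TAX_RANKS[j]]]
      groups <- split(hi[!is.na(lo) & !is.na(hi)], lo[!is.na(lo) & !is.na(hi)])
      if (any(vapply(groups, function(g) length(unique(g)) > 1, logical(1)))) {
        return(FALSE)
      }
    }
  }
  TRUE
}
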