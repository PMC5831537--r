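# Abundance co-occurrence: Pearson correlation of phage and host abundance
# profiles across samples, with pairwise exclusion of samples where either
# member is absent and a minimum-overlap rule. Sparse profiles correlate
# spuriously, hence both rules: samples with a zero in either profile are
# dropped per pair, and a correlation is only reported when more than six
# samples survive (>6, i.e. at least 7).

#' Read an abundance matrix
#'
#' TSV with genome ids in the first column (header `genome`) and one column
#' per sample; missing cells read as 0. Zero means absent.
#'
#' @param path TSV path.
#' @return Tibble, first column `genome`, remaining columns numeric sample
#'   abundances.
#' @export
read_abundance_tsv <- function(path) {
  # a malformed cell is reported through problems() below, not as a warning
  tbl <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      genome = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  ))
  if (!"genome" %in% names(tbl)) abort("abundance TSV must have a 'genome' column")
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    abort(sprintf("non-numeric abundance cell at row %d, column %d",
                  prob$row[1], prob$col[1]))
  }
  if (anyDuplicated(tbl$genome)) abort("duplicate genome ids in abundance table")
  tbl <- mutate(tbl, across(-"genome", ~ tidyr::replace_na(.x, 0)))
  if (any(as.matrix(tbl[, -1]) < 0)) abort("negative abundance values")
  tbl
}

#' Pairwise abundance correlation with exclusion rules
#'
#' Drops every sample where either profile is zero, then computes the
#' Pearson correlation over the remainder. Returns `NA` (no evidence) when
#' fewer than `min_shared` samples survive or when a surviving profile is
#' constant.
#'
#' @param phage_row,host_row Equal-length numeric abundance vectors.
#' @param min_shared Minimum number of mutually non-zero samples
#'   (default 7, i.e. "more than 6").
#' @return Pearson correlation in `[-1, 1]`, or `NA`.
#' @export
pair_correlation <- function(phage_row, host_row, min_shared = 7L) {
  if (length(phage_row) != length(host_row)) abort("profile length mismatch")
  keep <- phage_row > 0 & host_row > 0
  if (sum(keep) < min_shared) return(NA_real_)
  x <- phage_row[keep]; y <- host_row[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Abundance co-occurrence host scores
#'
#' Correlates every phage profile with every host profile under the
#' pairwise-exclusion and minimum-overlap rules. `NA` entries mean no
#' evidence, distinct from a low correlation.
#'
#' @param phage_ab,host_ab Abundance tibbles (first column `genome`) with
#'   identical sample columns in the same order.
#' @param min_shared See [pair_correlation()].
#' @param log_transform Correlate `log1p` abundances instead of raw values
#'   (off by default).
#' @return A score table, higher correlation = better.
#' @export
abundance_scores <- function(phage_ab, host_ab, min_shared = 7L,
                             log_transform = FALSE) {
  if (!identical(names(phage_ab)[-1], names(host_ab)[-1])) {
    abort("sample columns of phage and host abundance tables differ")
  }
  P <- as.matrix(phage_ab[, -1])
  H <- as.matrix(host_ab[, -1])
  if (log_transform) { P <- log1p(P); H <- log1p(H) }
  S <- matrix(NA_real_, nrow(P), nrow(H),
              dimnames = list(phage_ab$genome, host_ab$genome))
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(H))) {
      S[i, j] <- pair_correlation(P[i, ], H[j, ], min_shared)
    }
  }
  score_table_from_matrix(S, signal = "abundance", higher_is_better = TRUE)
}

#' Write an abundance tibble to TSV
#'
#' @param ab Abundance tibble.
#' @param path Output path.
#' @export
write_abundance_tsv <- function(ab, path) {
  readr::write_tsv(ab, path, progress = FALSE)
  invisible(path)
}
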