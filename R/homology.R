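# Nucleotide and translated homology summaries between phage and host
# genomes: (a) the union length of phage intervals covered by qualifying
# local alignments, and (b) the number of phage ORFs with a qualifying
# protein hit. The internal aligner is a deliberately simple seeded
# ungapped X-drop extender; the tabular adapter accepts externally computed
# 12-column alignment files so real BLAST hits can drive the same scoring.

# default thresholds (tunable): nucleotide alignment score floor ~ BLAST's
# word-derived default; protein floor on raw BLOSUM62 score
NT_PARAMS <- list(word = 11L, match = 1L, mismatch = -2L, xdrop = 20L, min_score = 28L)
AA_PARAMS <- list(word = 4L, xdrop = 20L, min_score = 50L)

blosum62 <- function() {
  if (is.null(.ph_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ph_cache$blosum62 <- e$BLOSUM62
  }
  .ph_cache$blosum62
}

# union length of 0-based half-open intervals
interval_union_length <- function(start, end) {
  if (length(start) == 0) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start + 1L, end))))
}

#' Nucleotide homology summary for one phage-host pair
#'
#' Finds local ungapped alignments seeded on exact 11-mers (match +1,
#' mismatch -2, X-drop 20) on both host strands, keeps those with score at
#' least `min_score`, and reports the total length of the phage covered by
#' at least one qualifying alignment (overlaps collapsed).
#'
#' @param phage_seq,host_seq Single nucleotide strings.
#' @param params List overriding `word`, `match`, `mismatch`, `xdrop`,
#'   `min_score`.
#' @param both_strands Search both host strands (default).
#' @return One-row tibble `total_aligned_len`, `n_hsps`, `best_score`.
#' @export
nucleotide_homology <- function(phage_seq, host_seq, params = list(),
                                both_strands = TRUE) {
  p <- utils::modifyList(NT_PARAMS, params)
  phage_seq <- clean_seq(phage_seq)
  host_seq <- clean_seq(host_seq)
  hsps <- nt_hsps_cpp(phage_seq, host_seq, p$word, p$match, p$mismatch,
                      p$xdrop, p$min_score)
  if (both_strands) {
    hsps2 <- nt_hsps_cpp(phage_seq, reverse_complement(host_seq), p$word,
                         p$match, p$mismatch, p$xdrop, p$min_score)
    hsps <- rbind(hsps, hsps2)
  }
  tibble(
    total_aligned_len = interval_union_length(hsps[, "qstart"], hsps[, "qend"]),
    n_hsps = nrow(hsps),
    best_score = if (nrow(hsps)) max(hsps[, "score"]) else 0
  )
}

#' Translated homology summary for one phage against a host proteome
#'
#' Translates each phage ORF and searches it against the host proteins by
#' exact 4-mer amino-acid seeding with ungapped BLOSUM62 extension. An ORF
#' matches when its best raw score reaches `min_score`; the summary is the
#' count of matching ORFs.
#'
#' @param phage_peptides Character vector of phage ORF peptides.
#' @param host_proteins Character vector of host protein sequences
#'   (non-empty).
#' @param params List overriding `word`, `xdrop`, `min_score`.
#' @return One-row tibble `n_matching_proteins`, `n_orfs`, `best_score`.
#' @export
translated_homology <- function(phage_peptides, host_proteins, params = list()) {
  p <- utils::modifyList(AA_PARAMS, params)
  if (length(host_proteins) == 0) abort("empty host protein set")
  if (length(phage_peptides) == 0) {
    return(tibble(n_matching_proteins = 0L, n_orfs = 0L, best_score = 0))
  }
  sm <- blosum62()
  best <- aa_best_scores_cpp(
    toupper(phage_peptides), toupper(host_proteins),
    sm, paste(rownames(sm), collapse = ""), p$word, p$xdrop
  )
  tibble(
    n_matching_proteins = sum(best >= p$min_score),
    n_orfs = length(phage_peptides),
    best_score = max(best)
  )
}

# peptides of one record (annotated CDS when available, called ORFs else)
record_peptides <- function(seq, cds = NULL, min_codons = 60L) {
  cs <- coding_seqs(seq, cds, min_codons = min_codons)
  if (length(cs$seqs) == 0) return(character())
  trimmed <- substring(cs$seqs, 1, (nchar(cs$seqs) %/% 3) * 3)
  peps <- sub("\\*$", "", translate_codons(trimmed))
  peps[nchar(peps) > 0]
}

#' Homology host scores
#'
#' Scores every phage against every host either by total qualifying
#' nucleotide alignment length (`mode = "nucleotide"`) or by the number of
#' phage ORFs with a qualifying protein hit (`mode = "translated"`).
#'
#' @param phages,hosts Sequence tibbles (optionally with a `cds` column).
#' @param mode `"nucleotide"` or `"translated"`.
#' @param params Threshold overrides, see [nucleotide_homology()] /
#'   [translated_homology()].
#' @param min_codons Minimum ORF length for called ORFs.
#' @return A score table, higher is better.
#' @export
homology_scores <- function(phages, hosts, mode = c("nucleotide", "translated"),
                            params = list(), min_codons = 60L) {
  mode <- match.arg(mode)
  S <- matrix(0, nrow(phages), nrow(hosts),
              dimnames = list(phages$id, hosts$id))
  if (mode == "nucleotide") {
    p <- utils::modifyList(NT_PARAMS, params)
    # both host strands per host, unioned on the phage; the phage is
    # indexed once per row
    queries <- c(rbind(hosts$seq, reverse_complement(hosts$seq)))
    group <- rep(seq_len(nrow(hosts)) - 1L, each = 2L)
    for (i in seq_len(nrow(phages))) {
      g <- nt_homology_groups_cpp(phages$seq[i], queries, group, p$word,
                                  p$match, p$mismatch, p$xdrop, p$min_score)
      S[i, ] <- g[, "union_len"]
    }
  } else {
    get_cds <- function(tbl, i) if ("cds" %in% names(tbl)) tbl$cds[[i]] else NULL
    phage_peps <- purrr::map(seq_len(nrow(phages)), function(i) {
      record_peptides(phages$seq[i], get_cds(phages, i), min_codons)
    })
    host_prots <- purrr::map(seq_len(nrow(hosts)), function(j) {
      record_peptides(hosts$seq[j], get_cds(hosts, j), min_codons)
    })
    for (i in seq_len(nrow(phages))) {
      for (j in seq_len(nrow(hosts))) {
        if (length(host_prots[[j]]) == 0 || length(phage_peps[[i]]) == 0) next
        S[i, j] <- translated_homology(phage_peps[[i]], host_prots[[j]],
                                       params = params)$n_matching_proteins
      }
    }
  }
  score_table_from_matrix(
    S, signal = paste0("homology_", mode), higher_is_better = TRUE
  )
}

#' Read a 12-column tabular alignment file
#'
#' Parses the standard tab-separated alignment format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore; 1-based inclusive coordinates) and
#' summarises it per (query, subject) pair the same way the internal scorer
#' does: `mode = "nucleotide"` collapses overlapping query intervals and
#' reports their union length; `mode = "translated"` counts distinct
#' queries (ORFs) with at least one hit.
#'
#' @param path Path to the tabular file (may be empty).
#' @param mode `"nucleotide"` or `"translated"`.
#' @return Tibble `phage_id`, `host_id` and `total_aligned_len` or
#'   `n_matching_proteins`. Translated mode expects query ids of the form
#'   `<phage_id>|<orf>`; plain ids are treated as one ORF each.
#' @export
read_tabular_hits <- function(path, mode = c("nucleotide", "translated")) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(if (mode == "nucleotide") {
      tibble(phage_id = character(), host_id = character(),
             total_aligned_len = integer())
    } else {
      tibble(phage_id = character(), host_id = character(),
             n_matching_proteins = integer())
    })
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad) > 0) {
    abort(sprintf("expected 12 tab-separated columns, got %d at line %d",
                  lengths(parts)[bad[1]], bad[1]))
  }
  m <- do.call(rbind, parts)
  hits <- tibble(
    query = m[, 1], subject = m[, 2],
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8])
  )
  if (mode == "nucleotide") {
    hits |>
      group_by(phage_id = .data$query, host_id = .data$subject) |>
      summarise(
        # 1-based inclusive input -> 0-based half-open
        total_aligned_len = interval_union_length(
          pmin(.data$qstart, .data$qend) - 1L, pmax(.data$qstart, .data$qend)
        ),
        .groups = "drop"
      )
  } else {
    hits |>
      mutate(phage_id = sub("\\|[^|]*$", "", .data$query)) |>
      group_by(.data$phage_id, host_id = .data$subject) |>
      summarise(n_matching_proteins = dplyr::n_distinct(.data$query),
                .groups = "drop")
  }
}
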