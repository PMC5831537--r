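# Run every signal over a benchmark bundle and score it at the six
# taxonomic ranks with the tie-aware rule, plus ROC/AUC per signal.

#' Available benchmark signals
#' @export
BENCHMARK_SIGNALS <- c(
  "exact_match", "homology_nucleotide", "homology_translated",
  "crispr_identity", "crispr_count", "kmer4", "codon", "gc", "abundance"
)

# detected spacers + one alignment pass, shared by both CRISPR signals
crispr_inputs <- function(bench) {
  spacers <- host_spacers(bench$hosts)
  hits <- if (nrow(spacers) > 0) crispr_spacer_hits(bench$phages, spacers)
  list(spacers = spacers, hits = hits)
}

# scores of 0 in match-based signals mean "nothing found": convert to
# no-evidence so the ties rule cannot score an evidence-free phage correct
zero_to_na <- function(tbl) {
  tbl$score[!is.na(tbl$score) & tbl$score == 0] <- NA_real_
  tbl
}

compute_signal <- function(signal, bench, min_codons = 60L, crispr = NULL) {
  if (is.null(crispr) && signal %in% c("crispr_identity", "crispr_count")) {
    crispr <- crispr_inputs(bench)
  }
  switch(signal,
    exact_match = zero_to_na(exact_match_scores(bench$phages, bench$hosts)),
    homology_nucleotide = zero_to_na(
      homology_scores(bench$phages, bench$hosts, mode = "nucleotide")
    ),
    homology_translated = zero_to_na(
      homology_scores(bench$phages, bench$hosts, mode = "translated",
                      min_codons = min_codons)
    ),
    crispr_identity = crispr_best_hit_scores(
      bench$phages, bench$hosts, spacers = crispr$spacers, hits = crispr$hits
    ),
    crispr_count = crispr_spacer_count_scores(
      bench$phages, bench$hosts, spacers = crispr$spacers, hits = crispr$hits
    ),
    kmer4 = composition_scores(bench$phages, bench$hosts, kind = "kmer", k = 4),
    codon = composition_scores(bench$phages, bench$hosts, kind = "codon",
                               min_codons = min_codons),
    gc = composition_scores(bench$phages, bench$hosts, kind = "gc"),
    abundance = abundance_scores(bench$phage_ab, bench$host_ab),
    abort(sprintf("unknown signal '%s'", signal))
  )
}

#' Run the phage-host benchmark
#'
#' Computes every requested signal's score table over the bundle, scores
#' the tie-aware top hosts at the six taxonomic ranks, and builds a ROC
#' curve per signal (no-evidence pairs excluded from the sweep). A signal
#' failing on the bundle is recorded and skipped; the run continues.
#'
#' @param bench A `ph_benchmark` from [build_benchmark()] (or any list
#'   with the same elements loaded from files).
#' @param signals Subset of [BENCHMARK_SIGNALS].
#' @param min_codons Minimum ORF length where ORF calling is needed.
#' @return A `ph_benchmark_result` with elements `scores` (named list of
#'   score tables), `accuracy` (tibble signal x rank), `roc` (named list of
#'   `ph_roc`), `errors` (named character), `truth`, `lineages`.
#' @export
run_benchmark <- function(bench, signals = BENCHMARK_SIGNALS, min_codons = 60L) {
  scores <- list(); errors <- character()
  crispr <- if (any(c("crispr_identity", "crispr_count") %in% signals)) {
    tryCatch(crispr_inputs(bench), error = function(e) NULL)
  }
  for (sg in signals) {
    res <- tryCatch(compute_signal(sg, bench, min_codons, crispr = crispr),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sg]] <- conditionMessage(res)
      warn(sprintf("signal '%s' failed and was skipped: %s", sg, errors[[sg]]))
    } else {
      attr(res, "signal") <- sg   # benchmark key, not the variant label
      scores[[sg]] <- res
    }
  }
  accuracy <- purrr::map_dfr(scores, function(tbl) {
    accuracy_at_rank(tbl, bench$truth, bench$lineages)
  })
  roc <- purrr::map(scores, function(tbl) {
    tryCatch(
      roc_curve(labelled_pairs(tbl, bench$truth),
                higher_is_better = higher_is_better(tbl)),
      error = function(e) NULL
    )
  })
  structure(
    list(scores = scores, accuracy = accuracy, roc = roc, errors = errors,
         truth = bench$truth, lineages = bench$lineages),
    class = "ph_benchmark_result"
  )
}

#' @export
print.ph_benchmark_result <- function(x, ...) {
  cat("phage-host benchmark:", length(x$scores), "signals,",
      length(unique(x$truth$phage)), "phages\n")
  print(glance(x))
  invisible(x)
}

#' Tidy a benchmark result
#'
#' @param x A `ph_benchmark_result`.
#' @param ... Unused.
#' @return The per-signal, per-rank accuracy tibble (`signal`, `rank`,
#'   `accuracy`, `n_phages`, `mean_set_size`).
#' @export
tidy.ph_benchmark_result <- function(x, ...) x$accuracy

#' @rdname tidy.ph_benchmark_result
#' @return `glance()`: one row per signal with `species_accuracy`, `auc`
#'   and `mean_set_size`.
#' @export
glance.ph_benchmark_result <- function(x, ...) {
  sp <- filter(x$accuracy, .data$rank == "species")
  tibble(
    signal = sp$signal,
    species_accuracy = sp$accuracy,
    auc = vapply(sp$signal, function(sg) {
      r <- x$roc[[sg]]
      if (is.null(r)) NA_real_ else attr(r, "auc")
    }, numeric(1)),
    mean_set_size = sp$mean_set_size
  )
}

#' @rdname tidy.ph_benchmark_result
#' @param object A `ph_benchmark_result`.
#' @export
autoplot.ph_benchmark_result <- function(object, ...) {
  acc <- mutate(object$accuracy,
                rank = factor(.data$rank, levels = TAX_RANKS))
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$signal, y = .data$accuracy,
                                    fill = .data$rank)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%d%%", round(100 * v))) +
    ggplot2::labs(x = NULL, y = "Correct host among top-scoring",
                  fill = "Rank") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Export benchmark outputs as TSV
#'
#' Writes one score TSV per signal, the ROC points, and the summary
#' accuracy table into `dir`.
#'
#' @param result A `ph_benchmark_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_benchmark <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sg in names(result$scores)) {
    readr::write_tsv(result$scores[[sg]],
                     file.path(dir, paste0("scores_", sg, ".tsv")),
                     progress = FALSE, na = "no_evidence")
    if (!is.null(result$roc[[sg]])) {
      readr::write_tsv(as_tibble(result$roc[[sg]]),
                       file.path(dir, paste0("roc_", sg, ".tsv")),
                       progress = FALSE)
    }
  }
  readr::write_tsv(result$accuracy, file.path(dir, "summary.tsv"),
                   progress = FALSE)
  invisible(dir)
}
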