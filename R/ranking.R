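# Score tables, tie-aware host ranking, six-rank accuracy, ROC curves and
# the random-assignment baseline.
#
# A score table is a long tibble (phage, host, score) carrying the signal
# name and its orientation as attributes. `NA` scores mean "no evidence"
# (e.g. a host without CRISPR arrays, too few shared samples) and are
# distinct from any numeric score: phages whose whole row is no-evidence
# predict nothing and are counted incorrect.

#' Build a score table
#'
#' @param x Tibble or data frame with columns `phage`, `host`, `score`
#'   (`NA` = no evidence).
#' @param signal Name of the signal that produced the scores.
#' @param higher_is_better `TRUE` when large scores indicate a better host
#'   (match lengths, correlations, counts), `FALSE` for distances.
#' @return A `ph_score_table` tibble.
#' @export
score_table <- function(x, signal, higher_is_better) {
  stopifnot(all(c("phage", "host", "score") %in% names(x)))
  out <- as_tibble(x)[, c("phage", "host", "score")]
  out$score <- as.numeric(out$score)
  attr(out, "signal") <- signal
  attr(out, "higher_is_better") <- isTRUE(higher_is_better)
  class(out) <- c("ph_score_table", class(tibble()))
  out
}

# matrix (phage rows x host cols) -> long score table
score_table_from_matrix <- function(S, signal, higher_is_better) {
  long <- tibble(
    phage = rep(rownames(S), times = ncol(S)),
    host = rep(colnames(S), each = nrow(S)),
    score = as.numeric(S)
  )
  score_table(long, signal, higher_is_better)
}

signal_name <- function(tbl) attr(tbl, "signal")
higher_is_better <- function(tbl) attr(tbl, "higher_is_better")

#' Top-scoring hosts for one phage, ties kept
#'
#' Returns every host attaining the row-optimal score under the table's
#' orientation. All tied hosts are returned, matching the rule that a
#' prediction is correct when the true host is among the tied optimum.
#' No-evidence rows give an empty prediction set.
#'
#' @param tbl A score table.
#' @param phage_id A phage id present in `tbl`.
#' @return Character vector of host ids (possibly empty).
#' @export
top_hosts <- function(tbl, phage_id) {
  rows <- tbl[tbl$phage == phage_id, ]
  if (nrow(rows) == 0) abort(sprintf("unknown phage id '%s'", phage_id))
  sc <- rows$score
  if (all(is.na(sc))) return(character())
  opt <- if (higher_is_better(tbl)) max(sc, na.rm = TRUE) else min(sc, na.rm = TRUE)
  rows$host[!is.na(sc) & sc == opt]
}

#' Prediction accuracy at taxonomic ranks
#'
#' Scores each phage's tie-aware top host set against the true host at the
#' six ranks. A phage is correct at a rank when any predicted host shares
#' the truth lineage name at that rank; phages with empty predictions count
#' incorrect. The mean prediction-set size is reported alongside so that
#' degenerate all-tied tables are visible.
#'
#' @param tbl A score table.
#' @param truth Tibble with columns `phage`, `host` (true host taxon).
#' @param lineages Lineage tibble from [read_lineage_table()] (or the same
#'   shape built in code) covering all hosts.
#' @param ranks Ranks to report (default all six).
#' @return Tibble with columns `signal`, `rank`, `accuracy`, `n_phages`,
#'   `mean_set_size` (mean over phages with a non-empty prediction; `NaN`
#'   when none).
#' @export
accuracy_at_rank <- function(tbl, truth, lineages, ranks = TAX_RANKS) {
  phages <- unique(tbl$phage)
  missing <- setdiff(phages, truth$phage)
  if (length(missing) > 0) {
    abort(sprintf("phage(s) missing from truth: %s", paste(missing, collapse = ", ")))
  }
  rank_names <- function(taxa, r) {
    tolower(lineages[[r]][match(taxa, lineages$taxon)])
  }
  sets <- purrr::map(phages, ~ top_hosts(tbl, .x))
  true_hosts <- truth$host[match(phages, truth$phage)]
  set_sizes <- lengths(sets)
  res <- purrr::map_dfr(ranks, function(r) {
    truth_at_r <- rank_names(true_hosts, r)
    correct <- purrr::map2_lgl(sets, truth_at_r, function(s, t) {
      if (length(s) == 0 || is.na(t)) return(FALSE)
      any(!is.na(rank_names(s, r)) & rank_names(s, r) == t)
    })
    tibble(rank = r, accuracy = mean(correct), n_phages = length(phages))
  })
  res$mean_set_size <- mean(set_sizes[set_sizes > 0])
  res$signal <- signal_name(tbl) %||% NA_character_
  res[, c("signal", "rank", "accuracy", "n_phages", "mean_set_size")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROC curve of a labelled score set
#'
#' Sweeps the score threshold from the optimum to the worst value; pairs
#' with equal scores enter together. The curve starts at (0, 0), ends at
#' (1, 1), and the area under it is computed by the trapezoid rule. The
#' diagonal is the behaviour of a random, indistinctive predictor.
#'
#' @param data Tibble with columns `score` (numeric; `NA` = no evidence,
#'   excluded) and `label` (logical, `TRUE` for a true phage-host pair).
#' @param higher_is_better Orientation of `score`.
#' @return A `ph_roc` tibble with columns `threshold`, `fp_rate`, `tp_rate`
#'   (first row is the (0, 0) origin with threshold `NA`); attribute `auc`.
#' @export
roc_curve <- function(data, higher_is_better = TRUE) {
  keep <- !is.na(data$score)
  sc <- data$score[keep]
  lab <- as.logical(data$label[keep])
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) abort("ROC needs at least one true and one false pair")
  key <- if (higher_is_better) -sc else sc
  ord <- order(key)
  sc <- sc[ord]; lab <- lab[ord]; key <- key[ord]
  last <- !duplicated(key, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(lab)[last] / n_pos
  fp <- cumsum(!lab)[last] / n_neg
  out <- tibble(
    threshold = c(NA_real_, sc[last]),
    fp_rate = c(0, fp),
    tp_rate = c(0, tp)
  )
  auc <- sum(diff(out$fp_rate) * (head(out$tp_rate, -1) + tail(out$tp_rate, -1)) / 2)
  attr(out, "auc") <- auc
  class(out) <- c("ph_roc", class(tibble()))
  out
}

#' @export
glance.ph_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_points = nrow(x) - 1L)
}

#' @rdname roc_curve
#' @param object A `ph_roc` tibble.
#' @param ... Unused.
#' @export
autoplot.ph_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fp_rate, y = .data$tp_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))
    )
}

# label the pairs of a score table against the truth (species-level pair
# identity) for ROC construction
labelled_pairs <- function(tbl, truth) {
  true_host <- truth$host[match(tbl$phage, truth$phage)]
  tibble(score = tbl$score, label = tbl$host == true_host)
}

#' Random host-assignment baseline
#'
#' Assigns each phage a uniformly random set of between `min(k)` and
#' `max(k)` hosts (set size itself uniform over `hosts_per_phage`) and
#' records the species-level accuracy per replicate. The closed-form
#' expectation is `mean(hosts_per_phage) / n_hosts`.
#'
#' @param truth Tibble with columns `phage`, `host`.
#' @param hosts Character vector: the candidate host pool.
#' @param hosts_per_phage Integer vector of allowed prediction-set sizes
#'   (default 1:4).
#' @param n_reps Number of Monte-Carlo replicates.
#' @return Tibble with columns `rep`, `accuracy`; attribute `expectation`
#'   holds the closed-form mean accuracy.
#' @export
random_baseline <- function(truth, hosts, hosts_per_phage = 1:4, n_reps = 100) {
  H <- length(hosts)
  if (max(hosts_per_phage) > H) abort("hosts_per_phage exceeds host pool size")
  acc <- vapply(seq_len(n_reps), function(r) {
    hit <- vapply(truth$host, function(th) {
      k <- hosts_per_phage[sample.int(length(hosts_per_phage), 1)]
      th %in% hosts[sample.int(H, k)]
    }, logical(1))
    mean(hit)
  }, numeric(1))
  out <- tibble(rep = seq_len(n_reps), accuracy = acc)
  attr(out, "expectation") <- mean(hosts_per_phage) / H
  out
}
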