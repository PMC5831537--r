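# CRISPR array detection, spacer extraction, and spacer-to-phage alignment
# under a short-query regime (match +1, mismatch -1, gap open 10, gap
# extend 2 -- the parameter set recommended for spacer-target searches).
#
# The array finder is a simplified repeat-spacer detector: exact seed words
# recurring with array-like spacing are chained, repeat boundaries are
# grown while the copies agree on a consensus, and the sequence between
# consecutive repeat copies becomes the spacers. It is not a port of any
# published finder; externally produced spacer FASTA can bypass detection
# entirely via read_spacer_fasta().

CRISPR_PARAMS <- list(
  seed_len = 21L,          # exact word shared by repeat copies
  repeat_len = c(21L, 48L),
  spacer_len = c(18L, 72L),
  min_copies = 3L,
  min_consensus_identity = 0.9,
  max_spacer_identity = 0.9, # guard against tandem repeats posing as arrays
  min_repeat_entropy = 1.0   # bits; rejects low-complexity (poly-N-like) repeats
)

# Shannon entropy (bits) of the base composition of a string
base_entropy <- function(s) {
  p <- table(strsplit(s, "")[[1]])
  p <- p / sum(p)
  -sum(p * log2(p))
}

# fraction of identical positions between two equal-length strings
str_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) return(0)
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

# majority consensus of equal-length strings + per-column agreement
consensus_cols <- function(strings) {
  m <- do.call(rbind, strsplit(strings, ""))
  cons <- apply(m, 2, function(col) names(which.max(table(col))))
  agree <- vapply(seq_len(ncol(m)), function(j) mean(m[, j] == cons[j]), numeric(1))
  list(consensus = paste(cons, collapse = ""), agreement = agree)
}

#' Detect CRISPR arrays in a host genome
#'
#' Reports repeat-spacer arrays with at least `min_copies` repeat copies,
#' repeat length within `repeat_len`, spacer lengths within `spacer_len`,
#' and copies at least `min_consensus_identity` identical to the repeat
#' consensus. Runs of near-identical "spacers" (tandem repeats) are
#' rejected.
#'
#' @param seq Host nucleotide string.
#' @param host_id Host identifier recorded in the output.
#' @param params Overrides for the detector defaults (`seed_len`,
#'   `repeat_len`, `spacer_len`, `min_copies`, `min_consensus_identity`,
#'   `max_spacer_identity`).
#' @return Tibble with one row per array: `host_id`, `array_index`,
#'   `start`, `end` (0-based half-open), `repeat_seq`, `n_copies`,
#'   `n_spacers`, and list-columns `repeat_starts` (0-based) and `spacers`.
#' @export
detect_crispr_arrays <- function(seq, host_id = "host", params = list()) {
  p <- utils::modifyList(CRISPR_PARAMS, params)
  seq <- clean_seq(seq)
  n <- nchar(seq)
  empty <- tibble(
    host_id = character(), array_index = integer(), start = integer(),
    end = integer(), repeat_seq = character(), n_copies = integer(),
    n_spacers = integer(), repeat_starts = list(), spacers = list()
  )
  k <- p$seed_len
  if (n < p$min_copies * (k + p$spacer_len[1])) return(empty)
  words <- substring(seq, 1:(n - k + 1), k:n)
  ord <- order(words)
  r <- rle(words[ord])
  rep_words <- r$values[r$lengths >= p$min_copies]
  if (length(rep_words) == 0) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  word_pos <- purrr::map(which(r$lengths >= p$min_copies), function(i) {
    sort(ord[starts[i]:ends[i]])
  })
  # gap between successive repeat starts = repeat_len + spacer_len
  gap_lo <- p$repeat_len[1] + p$spacer_len[1]
  gap_hi <- p$repeat_len[2] + p$spacer_len[2]
  # best-supported candidates first: a boundary-shifted pseudo-word can
  # recur at a subset of the true repeat positions and must not shadow it
  first_pos <- vapply(word_pos, function(x) x[1], numeric(1))
  o <- order(-lengths(word_pos), first_pos)
  word_pos <- word_pos[o]

  claimed <- logical(n)
  arrays <- list()
  for (pos in word_pos) {
    pos <- pos[!claimed[pos]]
    if (length(pos) < p$min_copies) next
    d <- diff(pos)
    ok <- d >= gap_lo & d <= gap_hi
    # maximal runs of positions chained by array-like gaps
    chains <- list(); cur <- pos[1]
    for (t in seq_along(d)) {
      if (ok[t]) cur <- c(cur, pos[t + 1])
      else { chains <- c(chains, list(cur)); cur <- pos[t + 1] }
    }
    chains <- c(chains, list(cur))
    for (chain in chains) {
      if (length(chain) < p$min_copies) next
      if (any(claimed[chain])) next
      arr <- grow_array(seq, chain, k, p)
      if (is.null(arr)) next
      claimed[(arr$start + 1):arr$end] <- TRUE
      arrays <- c(arrays, list(arr))
    }
  }
  if (length(arrays) == 0) return(empty)
  arrays <- arrays[order(vapply(arrays, function(a) a$start, numeric(1)))]
  purrr::map_dfr(seq_along(arrays), function(i) {
    a <- arrays[[i]]
    tibble(
      host_id = host_id, array_index = i, start = a$start, end = a$end,
      repeat_seq = a$repeat_seq, n_copies = a$n_copies,
      n_spacers = a$n_spacers, repeat_starts = list(a$repeat_starts),
      spacers = list(a$spacers)
    )
  })
}

# grow repeat boundaries around seed chain; returns array description or NULL
grow_array <- function(seq, chain, k, p) {
  n <- nchar(seq)
  min_gap <- min(diff(chain))
  max_rep <- min(p$repeat_len[2], min_gap - p$spacer_len[1])
  ext_ok <- function(offsets) {
    # offsets: candidate absolute start positions of a 1-bp column per copy
    if (any(offsets < 1 | offsets > n)) return(FALSE)
    col <- substring(seq, offsets, offsets)
    max(table(col)) / length(col) >= p$min_consensus_identity
  }
  L <- 0L; R <- 0L
  while (k + L + R < max_rep && ext_ok(chain - L - 1)) L <- L + 1L
  while (k + L + R < max_rep && ext_ok(chain + k + R)) R <- R + 1L
  rep_len <- k + L + R
  if (rep_len < p$repeat_len[1]) return(NULL)
  rep_starts <- chain - L                      # 1-based
  copies <- substring(seq, rep_starts, rep_starts + rep_len - 1)
  cc <- consensus_cols(copies)
  ident <- vapply(copies, str_identity, numeric(1), b = cc$consensus)
  if (any(ident < p$min_consensus_identity)) return(NULL)
  if (base_entropy(cc$consensus) < p$min_repeat_entropy) return(NULL)
  sp_start <- rep_starts[-length(rep_starts)] + rep_len
  sp_end <- rep_starts[-1] - 1
  sp_len <- sp_end - sp_start + 1
  if (any(sp_len < p$spacer_len[1] | sp_len > p$spacer_len[2])) return(NULL)
  spacers <- substring(seq, sp_start, sp_end)
  if (length(spacers) >= 2) {
    pairs <- utils::combn(spacers, 2)
    mean_id <- mean(apply(pairs, 2, function(x) str_identity(x[1], x[2])))
    if (mean_id >= p$max_spacer_identity) return(NULL)  # tandem repeat
  }
  list(
    start = rep_starts[1] - 1L,
    end = rep_starts[length(rep_starts)] + rep_len - 1L,
    repeat_seq = cc$consensus, n_copies = length(chain),
    n_spacers = length(spacers),
    repeat_starts = rep_starts - 1L, spacers = spacers
  )
}

#' Extract spacers from all hosts
#'
#' Runs [detect_crispr_arrays()] on each host and returns one row per
#' spacer with id `host|array|ordinal`. Hosts without arrays simply
#' contribute no rows (not every bacterium encodes a CRISPR system).
#'
#' @param hosts Sequence tibble.
#' @param params Detector overrides.
#' @return Tibble `spacer_id`, `host_id`, `array_index`, `ordinal`, `seq`.
#' @export
host_spacers <- function(hosts, params = list()) {
  purrr::map_dfr(seq_len(nrow(hosts)), function(i) {
    arr <- detect_crispr_arrays(hosts$seq[i], hosts$id[i], params)
    if (nrow(arr) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(arr)), function(a) {
      sp <- arr$spacers[[a]]
      tibble(
        spacer_id = sprintf("%s|%d|%d", arr$host_id[a], arr$array_index[a],
                            seq_along(sp)),
        host_id = arr$host_id[a], array_index = arr$array_index[a],
        ordinal = seq_along(sp), seq = sp
      )
    })
  })
}

#' Read / write spacer FASTA
#'
#' Spacer ids follow `host|array|ordinal`; anything after the first
#' whitespace in the header is ignored.
#'
#' @param path FASTA path.
#' @return `read_spacer_fasta()`: a spacer tibble as from [host_spacers()].
#' @export
read_spacer_fasta <- function(path) {
  recs <- read_fasta(path)
  parts <- strsplit(recs$id, "|", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad)) abort("spacer FASTA ids must be 'host|array|ordinal'")
  tibble(
    spacer_id = recs$id,
    host_id = vapply(parts, `[`, character(1), 1),
    array_index = as.integer(vapply(parts, `[`, character(1), 2)),
    ordinal = as.integer(vapply(parts, `[`, character(1), 3)),
    seq = recs$seq
  )
}

#' @rdname read_spacer_fasta
#' @param spacers Spacer tibble.
#' @export
write_spacer_fasta <- function(spacers, path) {
  write_fasta(tibble(id = spacers$spacer_id, seq = spacers$seq), path)
}

spacer_submat <- function() {
  if (is.null(.ph_cache$spacer_submat)) {
    b <- c("A", "C", "G", "T", "N")
    m <- matrix(-1, 5, 5, dimnames = list(b, b))
    diag(m) <- 1
    m["N", ] <- -1; m[, "N"] <- -1  # N matches nothing
    .ph_cache$spacer_submat <- m
  }
  .ph_cache$spacer_submat
}

#' Align spacers to a phage genome
#'
#' Aligns every spacer (both orientations) against the phage with the
#' short-query scoring regime: match +1, mismatch -1, gap opening 10, gap
#' extension 2. The whole spacer is aligned against the best-matching phage
#' substring, so coverage is full-length by construction; mismatches count
#' substitutions and gaps are reported separately. Hits with more than
#' `report_max_mismatch` substitutions are dropped.
#'
#' @param spacers Spacer tibble ([host_spacers()] / [read_spacer_fasta()]).
#' @param phage_seq Phage nucleotide string.
#' @param phage_id Phage identifier recorded in the output.
#' @param report_max_mismatch Reporting bound on substitutions (default 13,
#'   the degeneracy still recognised by CRISPR priming).
#' @return Tibble `spacer_id`, `host_id`, `phage_id`, `strand`, `start`,
#'   `end` (0-based half-open on the phage forward strand), `aligned_len`,
#'   `matches`, `mismatches`, `gaps`, `pct_identity`, `score`, `is_best`
#'   (best hit per spacer).
#' @export
match_spacers <- function(spacers, phage_seq, phage_id = "phage",
                          report_max_mismatch = 13L) {
  if (nrow(spacers) == 0) abort("no spacers supplied")
  phage_seq <- clean_seq(phage_seq)
  subject <- Biostrings::DNAString(phage_seq)
  one_orientation <- function(seqs, strand) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs), subject,
      type = "global-local", substitutionMatrix = spacer_submat(),
      gapOpening = 10, gapExtension = 2
    )
    ins <- Biostrings::insertion(Biostrings::nindel(aln))[, "WidthSum"]
    del <- Biostrings::deletion(Biostrings::nindel(aln))[, "WidthSum"]
    tibble(
      spacer_id = spacers$spacer_id, host_id = spacers$host_id,
      phage_id = phage_id, strand = strand,
      start = Biostrings::start(Biostrings::subject(aln)) - 1L,
      end = Biostrings::end(Biostrings::subject(aln)),
      aligned_len = Biostrings::nchar(aln),
      matches = Biostrings::nmatch(aln),
      mismatches = Biostrings::nmismatch(aln),
      gaps = ins + del,
      score = Biostrings::score(aln)
    )
  }
  hits <- bind_rows(
    one_orientation(spacers$seq, 1L),
    one_orientation(reverse_complement(spacers$seq), -1L)
  )
  hits$pct_identity <- 100 * hits$matches / hits$aligned_len
  hits <- hits[hits$mismatches <= report_max_mismatch, ]
  if (nrow(hits) == 0) return(hits |> mutate(is_best = logical()))
  hits |>
    group_by(.data$spacer_id) |>
    mutate(is_best = .data$score == max(.data$score)) |>
    ungroup()
}

# hits qualifying under a mismatch budget: substitutions within budget and
# raw score above the deterministic floor (gap penalties already paid in
# the score)
qualifying_hits <- function(hits, spacers, max_mismatch) {
  len <- nchar(spacers$seq)[match(hits$spacer_id, spacers$spacer_id)]
  gap_cost <- ifelse(hits$gaps > 0, 10 + 2 * hits$gaps, 0)
  hits[hits$mismatches <= max_mismatch &
         hits$score >= len - 2 * max_mismatch - gap_cost, ]
}

#' Spacer hits for a set of phages
#'
#' Runs [match_spacers()] for every phage and binds the hit tables. The
#' result can be passed to the score functions via their `hits` argument so
#' that mismatch-budget sweeps reuse one alignment pass.
#'
#' @param phages Sequence tibble.
#' @param spacers Spacer tibble.
#' @param report_max_mismatch See [match_spacers()].
#' @return A hit tibble.
#' @export
crispr_spacer_hits <- function(phages, spacers, report_max_mismatch = 13L) {
  purrr::map_dfr(seq_len(nrow(phages)), function(i) {
    match_spacers(spacers, phages$seq[i], phages$id[i],
                  report_max_mismatch = report_max_mismatch)
  })
}

#' CRISPR host scores
#'
#' `crispr_best_hit_scores()` scores a phage-host pair by the best percent
#' identity among the host's spacer hits with at most `max_mismatch`
#' substitutions (default 2; sweepable up to the 13-mismatch priming
#' bound). `crispr_spacer_count_scores()` scores by the number of distinct
#' spacers (identical spacer sequences within a host counted once) hitting
#' the phage within the budget; pairs with fewer than `min_spacers`
#' matching spacers are no-evidence. Hosts without detected arrays yield
#' no-evidence entries throughout.
#'
#' @param phages Sequence tibble.
#' @param hosts Sequence tibble (ignored when `spacers` is supplied, except
#'   to fix the host universe of the table).
#' @param spacers Optional precomputed spacer tibble; defaults to
#'   [host_spacers()] on `hosts`.
#' @param max_mismatch Substitution budget for a qualifying hit.
#' @param params Detector overrides for the default spacer extraction.
#' @param hits Optional precomputed hit tibble from [crispr_spacer_hits()]
#'   (lets mismatch-budget sweeps reuse one alignment pass).
#' @return A score table, higher is better; `NA` = no evidence.
#' @export
crispr_best_hit_scores <- function(phages, hosts, spacers = NULL,
                                   max_mismatch = 2L, params = list(),
                                   hits = NULL) {
  if (is.null(spacers)) spacers <- host_spacers(hosts, params)
  S <- matrix(NA_real_, nrow(phages), nrow(hosts),
              dimnames = list(phages$id, hosts$id))
  if (nrow(spacers) > 0) {
    if (is.null(hits)) hits <- crispr_spacer_hits(phages, spacers)
    hits <- qualifying_hits(hits, spacers, max_mismatch)
    if (nrow(hits) > 0) {
      agg <- hits |>
        group_by(.data$phage_id, .data$host_id) |>
        summarise(best = max(.data$pct_identity), .groups = "drop")
      S[cbind(agg$phage_id, agg$host_id)] <- agg$best
    }
  }
  score_table_from_matrix(S, signal = "crispr_identity", higher_is_better = TRUE)
}

#' @rdname crispr_best_hit_scores
#' @param min_spacers Minimum number of distinct matching spacers for a
#'   pair to count as evidence (default 1; 2 gives the more specific
#'   multi-spacer variant).
#' @export
crispr_spacer_count_scores <- function(phages, hosts, spacers = NULL,
                                       max_mismatch = 2L, min_spacers = 1L,
                                       params = list(), hits = NULL) {
  if (is.null(spacers)) spacers <- host_spacers(hosts, params)
  S <- matrix(NA_real_, nrow(phages), nrow(hosts),
              dimnames = list(phages$id, hosts$id))
  if (nrow(spacers) > 0) {
    if (is.null(hits)) hits <- crispr_spacer_hits(phages, spacers)
    hits <- qualifying_hits(hits, spacers, max_mismatch)
    if (nrow(hits) > 0) {
      hits$spacer_seq <- spacers$seq[match(hits$spacer_id, spacers$spacer_id)]
      agg <- hits |>
        group_by(.data$phage_id, .data$host_id) |>
        summarise(count = dplyr::n_distinct(.data$spacer_seq), .groups = "drop") |>
        filter(.data$count >= min_spacers)
      if (nrow(agg) > 0) S[cbind(agg$phage_id, agg$host_id)] <- agg$count
    }
  }
  score_table_from_matrix(S, signal = "crispr_count", higher_is_better = TRUE)
}
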