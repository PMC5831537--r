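# Longest exact match between phage and host genomes: shared 15-mers are
# found by hashing, then co-diagonal seeds whose start positions differ by
# at most the seed length are merged. Because a mismatch on a diagonal
# forces a gap of at least seed_len + 1 between seed starts, the merged
# runs are exactly the maximal identical stretches of length >= seed_len;
# no base-by-base extension is required.

# integer-encode every k-mer window of a sequence (base-4, first base most
# significant); windows containing N are NA. Returns numeric vector of
# length nchar(seq) - k + 1 (window i starts at position i, 1-based).
kmer_codes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  lut <- rep(NA_real_, 128)
  lut[utf8ToInt("A")] <- 0; lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2; lut[utf8ToInt("T")] <- 3
  v <- lut[utf8ToInt(seq)]
  m <- embed(v, k)               # row i = v[i+k-1], ..., v[i]
  as.numeric(m %*% 4^(0:(k - 1)))
}

#' Build a seed index over host genomes
#'
#' Precomputes, per host and strand, the sorted integer codes of all
#' `seed_len`-mers together with their positions, so that the shared seeds
#' of any phage can be retrieved by binary search. Hosts are processed one
#' record at a time.
#'
#' @param hosts Sequence tibble.
#' @param seed_len Seed length in bp (>= 8; default 15).
#' @param both_strands Also index the reverse complement of each host.
#' @return An opaque index object for [longest_exact_match()] /
#'   [exact_match_scores()].
#' @export
build_seed_index <- function(hosts, seed_len = 15L, both_strands = TRUE) {
  stopifnot(seed_len >= 8)
  strands <- if (both_strands) c(1L, -1L) else 1L
  entries <- list()
  for (i in seq_len(nrow(hosts))) {
    for (st in strands) {
      s <- if (st == 1L) hosts$seq[i] else reverse_complement(hosts$seq[i])
      codes <- kmer_codes(s, seed_len)
      ord <- order(codes, na.last = NA)     # drops N-containing windows
      entries[[paste(hosts$id[i], st)]] <- list(
        host = hosts$id[i], strand = st, len = nchar(s),
        sorted = codes[ord], pos = ord
      )
    }
  }
  structure(
    list(entries = entries, seed_len = as.integer(seed_len),
         hosts = hosts$id, both_strands = both_strands),
    class = "ph_seed_index"
  )
}

# positions (1-based) of a seed code in one index entry
lookup_seed <- function(index, host_id, code, strand = 1L) {
  e <- index$entries[[paste(host_id, strand)]]
  if (is.null(e)) abort(sprintf("host '%s' strand %d not in index", host_id, strand))
  lo <- findInterval(code - 0.5, e$sorted)
  hi <- findInterval(code, e$sorted)
  if (hi <= lo) integer(0) else sort(e$pos[(lo + 1):hi])
}

# best merged co-diagonal run for one phage against one index entry;
# list(length, phage_pos, host_pos) 0-based, or NULL
best_run <- function(pcodes, entry, k) {
  lo <- findInterval(pcodes - 0.5, entry$sorted)
  hi <- findInterval(pcodes, entry$sorted)
  sel <- which(!is.na(pcodes) & hi > lo)
  if (length(sel) == 0) return(NULL)
  counts <- hi[sel] - lo[sel]
  ppos <- rep(sel, counts)
  idx <- sequence(counts) + rep(lo[sel], counts)
  hpos <- entry$pos[idx]
  dg <- ppos - hpos
  o <- order(dg, ppos)
  dg <- dg[o]; pp <- ppos[o]; hp <- hpos[o]
  nb <- length(pp)
  newrun <- c(TRUE, dg[-1] != dg[-nb] | (pp[-1] - pp[-nb]) > k)
  firsts <- which(newrun)
  lasts <- c(firsts[-1] - 1L, nb)
  lens <- pp[lasts] - pp[firsts] + k
  b <- which.max(lens)
  list(
    length = lens[b],
    phage_pos = pp[firsts[b]] - 1L,   # 0-based
    host_pos_on_strand = hp[firsts[b]] - 1L
  )
}

#' Longest exact match between a phage and one host
#'
#' @param phage_seq A single phage nucleotide string.
#' @param host_id Host id present in `index`.
#' @param index A seed index from [build_seed_index()].
#' @return One-row tibble (`length`, `phage_pos`, `host_pos`, `strand`;
#'   positions 0-based on the forward strands) or a zero-row tibble when no
#'   seed is shared. `host_pos` is the forward-strand start of the matching
#'   host region for either strand.
#' @export
longest_exact_match <- function(phage_seq, host_id, index) {
  k <- index$seed_len
  pcodes <- kmer_codes(clean_seq(phage_seq), k)
  best <- NULL
  for (st in if (index$both_strands) c(1L, -1L) else 1L) {
    e <- index$entries[[paste(host_id, st)]]
    if (is.null(e)) abort(sprintf("host '%s' not in index", host_id))
    r <- best_run(pcodes, e, k)
    if (!is.null(r) && (is.null(best) || r$length > best$length)) {
      # map reverse-strand coordinates back to the host forward strand
      host_pos <- if (st == 1L) r$host_pos_on_strand else {
        e$len - r$host_pos_on_strand - r$length
      }
      best <- list(length = r$length, phage_pos = r$phage_pos,
                   host_pos = host_pos, strand = st)
    }
  }
  if (is.null(best)) {
    return(tibble(length = integer(), phage_pos = integer(),
                  host_pos = integer(), strand = integer()))
  }
  tibble(length = best$length, phage_pos = best$phage_pos,
         host_pos = best$host_pos, strand = best$strand)
}

#' Longest-exact-match host scores
#'
#' Scores every phage against every host by the length of their longest
#' identical stretch (0 when no `seed_len`-mer is shared). Multiple hosts can
#' attain the same longest match; ties are preserved in the table.
#'
#' @param phages,hosts Sequence tibbles.
#' @param seed_len Seed length (default 15).
#' @param both_strands Search the phage against both host strands
#'   (default); `FALSE` restricts to forward-forward.
#' @param index Optionally a prebuilt [build_seed_index()] over `hosts`.
#' @return A score table, higher is better.
#' @export
exact_match_scores <- function(phages, hosts, seed_len = 15L,
                               both_strands = TRUE, index = NULL) {
  if (is.null(index)) index <- build_seed_index(hosts, seed_len, both_strands)
  S <- matrix(0L, nrow(phages), ncol = length(index$hosts),
              dimnames = list(phages$id, index$hosts))
  for (i in seq_len(nrow(phages))) {
    pcodes <- kmer_codes(phages$seq[i], index$seed_len)
    for (h in index$hosts) {
      best <- 0L
      for (st in if (index$both_strands) c(1L, -1L) else 1L) {
        r <- best_run(pcodes, index$entries[[paste(h, st)]], index$seed_len)
        if (!is.null(r)) best <- max(best, r$length)
      }
      S[i, h] <- best
    }
  }
  score_table_from_matrix(S, signal = "exact_match", higher_is_better = TRUE)
}

#' Per-pair exact-match detail table
#'
#' One row per phage-host pair whose longest identical stretch reaches the
#' seed length, with coordinates and strand; suitable for TSV export and for
#' building match-length histograms split by correct vs incorrect host.
#'
#' @inheritParams exact_match_scores
#' @return Tibble `phage_id, host_id, length, phage_start, host_start, strand`.
#' @export
exact_match_table <- function(phages, hosts, seed_len = 15L, both_strands = TRUE) {
  index <- build_seed_index(hosts, seed_len, both_strands)
  purrr::map_dfr(seq_len(nrow(phages)), function(i) {
    purrr::map_dfr(hosts$id, function(h) {
      m <- longest_exact_match(phages$seq[i], h, index)
      if (nrow(m) == 0) return(NULL)
      tibble(phage_id = phages$id[i], host_id = h, length = m$length,
             phage_start = m$phage_pos, host_start = m$host_pos,
             strand = m$strand)
    })
  })
}

#' Match-length histogram (correct vs incorrect hosts)
#'
#' Bins the longest exact match of each phage (all tied longest hosts
#' included) and splits counts by whether the host is the true one.
#'
#' @param matches Output of [exact_match_table()].
#' @param truth Tibble `phage`, `host`.
#' @param binwidth Histogram bin width in bp (log2-spaced bins are often
#'   more informative; this export keeps plain bp bins).
#' @return Tibble `bin_start`, `bin_end`, `correct`, `n`.
#' @export
exact_match_histogram <- function(matches, truth, binwidth = 50) {
  best <- matches |>
    group_by(.data$phage_id) |>
    filter(.data$length == max(.data$length)) |>
    ungroup()
  true_host <- truth$host[match(best$phage_id, truth$phage)]
  best$correct <- best$host_id == true_host
  best$bin_start <- (best$length %/% binwidth) * binwidth
  best |>
    group_by(.data$bin_start, .data$correct) |>
    summarise(n = n(), .groups = "drop") |>
    mutate(bin_end = .data$bin_start + binwidth) |>
    select("bin_start", "bin_end", "correct", "n")
}
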