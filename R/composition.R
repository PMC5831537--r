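# Canonical oligonucleotide usage profiles, codon usage, GC content, and
# profile distances. A k-mer and its reverse complement are counted into a
# single canonical bin (the lexicographically smaller of the pair), so
# profiles are strand-invariant: odd k gives 4^k / 2 bins, even k gives
# 2^k + (4^k - 2^k) / 2 bins (the 2^k palindromic words are their own bin).

# canonical word map for one k, cached: list(words, canon, bins)
canonical_map <- function(k) {
  key <- paste0("canon_", k)
  if (!is.null(.ph_cache[[key]])) return(.ph_cache[[key]])
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  canon <- ifelse(words <= rc, words, rc)
  bins <- sort(unique(canon))
  .ph_cache[[key]] <- list(words = words, canon = canon, bins = bins)
  .ph_cache[[key]]
}

#' Dimension of a canonical k-mer profile
#'
#' `4^k / 2` for odd `k`; `2^k + (4^k - 2^k) / 2` for even `k` (each of the
#' `2^k` palindromic even-length words is its own reverse complement).
#'
#' @param k Word length, 1-8.
#' @return Integer number of canonical bins.
#' @examples
#' canonical_kmer_dim(3) # 32
#' canonical_kmer_dim(8) # 32896
#' @export
canonical_kmer_dim <- function(k) {
  stopifnot(k >= 1, k <= 8)
  if (k %% 2 == 1) 4^k / 2 else 2^k + (4^k - 2^k) / 2
}

new_profile <- function(bins, freq, kind, dim, source = NULL) {
  out <- tibble(word = bins, freq = as.numeric(freq))
  attr(out, "kind") <- kind
  attr(out, "profile_dim") <- dim
  if (!is.null(source)) attr(out, "source") <- source
  class(out) <- c("ph_profile", class(out))
  out
}

#' Canonical k-mer usage profile
#'
#' Counts every window of length `k` on the forward strand into the canonical
#' bin shared by the word and its reverse complement, then normalises counts
#' to relative frequencies. Windows containing `N` are skipped. Profiles are
#' invariant under reverse complementing the input.
#'
#' @param seq A single nucleotide string with `nchar(seq) >= k`.
#' @param k Word length, 1-8.
#' @return A profile tibble with columns `word` (canonical representative,
#'   lexicographic order) and `freq` (sums to 1); attributes `kind` and
#'   `profile_dim`.
#' @export
canonical_kmer_profile <- function(seq, k) {
  if (k < 1 || k > 8) abort("k must be in 1..8")
  stopifnot(length(seq) == 1)
  seq <- clean_seq(seq)
  if (nchar(seq) < k) abort("sequence shorter than k")
  cm <- canonical_map(k)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq), width = k)
  binned <- rowsum(as.numeric(counts), group = cm$canon)[cm$bins, 1]
  total <- sum(binned)
  if (total == 0) abort("no countable windows (all contain N)")
  new_profile(cm$bins, binned / total, kind = paste0("kmer", k),
              dim = canonical_kmer_dim(k))
}

#' GC content profile
#'
#' The k = 1 special case: a two-element vector of (A/T frequency, G/C
#' frequency) over the non-`N` positions.
#'
#' @param seq A single nucleotide string.
#' @return A profile tibble with bins `AT` and `GC`.
#' @export
gc_profile <- function(seq) {
  stopifnot(length(seq) == 1)
  seq <- clean_seq(seq)
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(seq), letters = c("A", "C", "G", "T"))
  total <- sum(cnt)
  if (total == 0) abort("no countable bases (all N)")
  new_profile(c("AT", "GC"), c(cnt["A"] + cnt["T"], cnt["C"] + cnt["G"]) / total,
              kind = "gc", dim = 2L)
}

#' Codon usage profile
#'
#' In-frame codon frequencies pooled over all coding regions of a record
#' (strand-resolved), a 64-element vector including the stop codons.
#' Annotated CDS intervals are used when supplied; otherwise ORFs are called
#' with [find_orfs()] and the profile source is recorded in the `source`
#' attribute (`"annotated"` or `"orf"`).
#'
#' @param seq A single nucleotide string.
#' @param cds Optional CDS table (`start`, `end`, `strand`; 0-based half-open).
#' @param min_codons Minimum ORF length when calling ORFs.
#' @return A profile tibble with 64 codon bins.
#' @export
codon_profile <- function(seq, cds = NULL, min_codons = 60L) {
  seq <- clean_seq(seq)
  cs <- coding_seqs(seq, cds, min_codons = min_codons)
  if (length(cs$seqs) == 0) abort("no coding regions found")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(cs$seqs), width = 3, step = 3
  )
  total <- colSums(counts)
  if (sum(total) == 0) abort("no countable codons")
  new_profile(names(total), total / sum(total), kind = "codon", dim = 64L,
              source = cs$source)
}

#' Distance between two composition profiles
#'
#' @param p,q Profile tibbles of the same kind and dimension.
#' @param metric One of `"euclidean"` (default), `"manhattan"`,
#'   `"cosine"` (1 - cosine similarity) or `"pearson"` (correlation, in
#'   `[-1, 1]`, higher = more similar).
#' @return A single numeric value.
#' @export
profile_distance <- function(p, q,
                             metric = c("euclidean", "manhattan", "cosine", "pearson")) {
  metric <- match.arg(metric)
  if (!identical(attr(p, "kind"), attr(q, "kind")) || nrow(p) != nrow(q)) {
    abort("profile kind/dimension mismatch")
  }
  x <- p$freq; y <- q$freq
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    cosine = 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
    pearson = cor(x, y)
  )
}

# profile matrix (rows = records) for a sequence table; failing records are
# dropped with a warning; returns list(mat, ids)
profile_matrix <- function(records, kind, k, min_codons = 60L) {
  profs <- purrr::map(seq_len(nrow(records)), function(i) {
    tryCatch(
      switch(kind,
        kmer = canonical_kmer_profile(records$seq[i], k),
        gc = gc_profile(records$seq[i]),
        codon = codon_profile(
          records$seq[i],
          cds = if ("cds" %in% names(records)) records$cds[[i]] else NULL,
          min_codons = min_codons
        )
      ),
      error = function(e) NULL
    )
  })
  ok <- !vapply(profs, is.null, logical(1))
  if (!all(ok)) {
    warn(sprintf(
      "composition profile failed for %d record(s), dropped: %s",
      sum(!ok), paste(records$id[!ok], collapse = ", ")
    ))
  }
  mat <- do.call(rbind, purrr::map(profs[ok], "freq"))
  rownames(mat) <- records$id[ok]
  mat
}

#' Composition profiles for a set of genomes, wide format
#'
#' One row per genome, one column per canonical word (lexicographic order
#' of representatives) — the layout used for TSV export. Records whose
#' profile cannot be computed are dropped with a warning.
#'
#' @inheritParams composition_scores
#' @param records Sequence tibble.
#' @return Wide tibble: `genome` plus one numeric column per bin.
#' @export
composition_profiles <- function(records, kind = c("kmer", "codon", "gc"),
                                 k = 4, min_codons = 60L) {
  kind <- match.arg(kind)
  mat <- profile_matrix(records, kind, k, min_codons)
  if (is.null(mat) || nrow(mat) == 0) abort("no computable profiles")
  bins <- switch(kind,
    kmer = canonical_map(k)$bins,
    codon = Biostrings::mkAllStrings(c("A", "C", "G", "T"), 3),
    gc = c("AT", "GC")
  )
  colnames(mat) <- bins
  bind_cols(tibble(genome = rownames(mat)), as_tibble(mat))
}

#' Composition-based host scores
#'
#' Scores every phage against every candidate host by the distance (or
#' correlation) between their composition profiles. Distances are computed on
#' relative frequencies so genome length cancels; the default follows the
#' smallest-Euclidean-distance rule on tetranucleotide profiles.
#'
#' @param phages,hosts Sequence tibbles.
#' @param kind `"kmer"`, `"codon"` or `"gc"`.
#' @param k Word length for `kind = "kmer"`.
#' @param metric See [profile_distance()]; `"pearson"` flips the orientation
#'   to higher-is-better.
#' @param min_codons Minimum ORF length when codon profiles fall back to ORF
#'   calling.
#' @return A score table (see [score_table()]); lower is better for distance
#'   metrics.
#' @export
composition_scores <- function(phages, hosts, kind = c("kmer", "codon", "gc"),
                               k = 4, metric = "euclidean", min_codons = 60L) {
  kind <- match.arg(kind)
  P <- profile_matrix(phages, kind, k, min_codons)
  H <- profile_matrix(hosts, kind, k, min_codons)
  if (is.null(P) || is.null(H) || nrow(P) == 0 || nrow(H) == 0) {
    abort("no computable profiles")
  }
  S <- switch(metric,
    euclidean = {
      d2 <- outer(rowSums(P^2), rowSums(H^2), "+") - 2 * P %*% t(H)
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      out <- matrix(0, nrow(P), nrow(H))
      for (j in seq_len(nrow(H))) out[, j] <- rowSums(abs(sweep(P, 2, H[j, ])))
      out
    },
    cosine = {
      sim <- (P %*% t(H)) / outer(sqrt(rowSums(P^2)), sqrt(rowSums(H^2)))
      1 - sim
    },
    pearson = cor(t(P), t(H)),
    abort(sprintf("unknown metric '%s'", metric))
  )
  dimnames(S) <- list(rownames(P), rownames(H))
  signal <- if (kind == "kmer") sprintf("kmer%d_%s", k, metric) else paste0(kind, "_", metric)
  score_table_from_matrix(S, signal = signal,
                          higher_is_better = metric == "pearson")
}
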