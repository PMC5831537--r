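# Shared fixture builders. Everything is generated in code; tests set their
# own seeds.

BASES4 <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES4, n, replace = TRUE), collapse = "")

substitute_n <- function(s, n_sub) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), n_sub)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES4, b), 1), character(1))
  paste(ch, collapse = "")
}

# independent longest-common-substring oracle: binary search over the
# candidate length, testing existence via intersection of substring sets
# (no seeding/diagonal logic shared with the implementation)
lcs_forward <- function(a, b) {
  subs <- function(s, L) unique(substring(s, 1:(nchar(s) - L + 1), L:nchar(s)))
  has_common <- function(L) {
    L <= nchar(a) && L <= nchar(b) && length(intersect(subs(a, L), subs(b, L))) > 0
  }
  lo <- 0L; hi <- min(nchar(a), nchar(b))
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (has_common(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

lcs_both_strands <- function(a, b) {
  max(lcs_forward(a, b), lcs_forward(a, reverse_complement(b)))
}

# small planted CRISPR host: returns list(seq, repeat_seq, spacers)
planted_array_host <- function(flank = 3000, repeat_len = 28, spacer_len = 32,
                               n_spacers = 3) {
  rep_seq <- rand_seq(repeat_len)
  repeat {  # unambiguous boundaries: spacer first/last bases not all equal
    spacers <- replicate(n_spacers, rand_seq(spacer_len))
    if (phagehost:::spacer_boundaries_ok(spacers)) break
  }
  arr <- paste0(paste0(rep_seq, spacers, collapse = ""), rep_seq)
  list(
    seq = paste0(rand_seq(flank), arr, rand_seq(flank)),
    repeat_seq = rep_seq, spacers = spacers,
    array_start = flank, array_end = flank + nchar(arr)
  )
}

# tree-consistent toy lineage table for n hosts (ids host1..hostn)
toy_lineage_tbl <- function(ids) {
  i <- seq_along(ids)
  tibble::tibble(
    taxon = ids,
    species = paste0("s", i),
    genus = paste0("g", ceiling(i / 2)),
    family = paste0("f", ceiling(i / 4)),
    order = paste0("o", ceiling(i / 8)),
    class = paste0("c", ceiling(i / 16)),
    phylum = paste0("p", ceiling(i / 32))
  )
}

# full default-scale benchmark plus signal run, built once and shared by the
# acceptance tests
full_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      bench <- build_benchmark(fixture_config(seed = 1))
      res <- suppressWarnings(run_benchmark(bench))
      spacers <- host_spacers(bench$hosts)
      hits <- crispr_spacer_hits(bench$phages, spacers)
      cache <<- list(bench = bench, res = res, spacers = spacers, hits = hits)
    }
    cache
  }
})

# one small cached benchmark shared by the deeper tests (built once per run)
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_benchmark(fixture_config(
        n_hosts = 10L, host_len = 12000L, n_phages = 10L, phage_len = 6000L,
        n_samples = 30L, seed = 42L
      ))
    }
    cache
  }
})
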