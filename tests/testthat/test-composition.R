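# brute-force canonical dimension: enumerate all 4^k words, collapse each
# with its reverse complement, count distinct pairs
brute_canonical_dim <- function(k) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  length(unique(pmin(words, rc)))
}

test_that("canonical k-mer dimensionality matches brute-force enumeration for k = 1..8", {
  for (k in 1:8) expect_equal(canonical_kmer_dim(k), brute_canonical_dim(k))
  expect_equal(canonical_kmer_dim(3), 32)
  expect_equal(canonical_kmer_dim(8), 32896)
  expect_equal(canonical_kmer_dim(2), 10)
})

test_that("k-mer profiles are normalised, strand-invariant, and skip N windows", {
  set.seed(51)
  for (k in c(1, 2, 4, 5)) {
    s <- rand_seq(500)
    p <- canonical_kmer_profile(s, k)
    expect_equal(nrow(p), canonical_kmer_dim(k))
    expect_equal(sum(p$freq), 1, tolerance = 1e-9)
    q <- canonical_kmer_profile(reverse_complement(s), k)
    expect_equal(p$freq, q$freq, tolerance = 1e-12)
  }
  # N windows skipped: profile of ACGTNACGT at k=4 counts only the 2 clean windows
  p <- canonical_kmer_profile("ACGTNACGT", 4)
  expect_equal(sum(p$freq > 0), 1)  # ACGT is palindromic canonical bin
  expect_error(canonical_kmer_profile("ACGT", 9), "1..8")
  expect_error(canonical_kmer_profile("AC", 4), "shorter")
})

test_that("GC profile handles the stated special cases and equals the k=1 profile", {
  expect_equal(gc_profile("GGCC")$freq, c(0, 1))
  expect_equal(gc_profile("ACGT")$freq, c(0.5, 0.5))
  expect_equal(canonical_kmer_profile("AAAA", 1)$freq, c(1, 0))
  expect_error(gc_profile("NNN"), "all N")
  set.seed(52)
  for (i in 1:20) {
    s <- rand_seq(sample(10:300, 1))
    expect_equal(gc_profile(s)$freq, canonical_kmer_profile(s, 1)$freq,
                 tolerance = 1e-12)
  }
})

test_that("codon profile is 64-dimensional and pools CDS counts by weight", {
  cds1 <- data.frame(start = 0, end = 9, strand = 1)
  p <- codon_profile("ATGAAATAA", cds = cds1)
  expect_equal(nrow(p), 64)
  expect_equal(sum(p$freq), 1, tolerance = 1e-12)
  expect_equal(p$freq[p$word %in% c("ATG", "AAA", "TAA")], rep(1 / 3, 3))
  # pooled profile equals count-weighted mean of per-CDS profiles
  set.seed(53)
  g1 <- paste0("ATG", rand_seq(30), "TAA")  # may contain internal stops; fine for counting
  g2 <- paste0("ATG", rand_seq(60), "TAA")
  s <- paste0(g1, g2)
  cds <- data.frame(start = c(0, nchar(g1)), end = c(nchar(g1), nchar(s)), strand = 1)
  pooled <- codon_profile(s, cds = cds)
  p1 <- codon_profile(g1, cds = data.frame(start = 0, end = nchar(g1), strand = 1))
  p2 <- codon_profile(g2, cds = data.frame(start = 0, end = nchar(g2), strand = 1))
  w <- c(nchar(g1), nchar(g2)) / 3
  expect_equal(pooled$freq, (w[1] * p1$freq + w[2] * p2$freq) / sum(w),
               tolerance = 1e-12)
  # reverse-strand CDS resolved before counting
  rc <- reverse_complement("ATGAAATAA")
  pr <- codon_profile(rc, cds = data.frame(start = 0, end = 9, strand = -1))
  expect_equal(pr$freq, p$freq)
  expect_error(codon_profile(strrep("CCC", 30)), "no coding")
})

test_that("profile distances match direct formula oracles", {
  p <- canonical_kmer_profile("ACGTACGGGT", 2)
  expect_equal(profile_distance(p, p), 0)
  mk <- function(v) {
    out <- tibble::tibble(word = paste0("w", seq_along(v)), freq = v)
    attr(out, "kind") <- "test"
    out
  }
  expect_equal(profile_distance(mk(c(1, 0)), mk(c(0, 1))), sqrt(2))
  set.seed(54)
  for (i in 1:10) {
    x <- runif(8); y <- runif(8)
    expect_equal(profile_distance(mk(x), mk(y)), sqrt(sum((x - y)^2)),
                 tolerance = 1e-12)
    expect_equal(profile_distance(mk(x), mk(y), "manhattan"), sum(abs(x - y)))
    expect_equal(profile_distance(mk(x), mk(y), "pearson"), cor(x, y))
    expect_equal(profile_distance(mk(x), mk(y), "cosine"),
                 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2)))
  }
  q3 <- canonical_kmer_profile("ACGTACGGGT", 3)
  expect_error(profile_distance(p, q3), "mismatch")
})

test_that("wide profile tables export one row per genome over canonical bins", {
  set.seed(56)
  recs <- seq_tbl(c("g1", "g2"), c(rand_seq(300), rand_seq(500)))
  wide <- composition_profiles(recs, kind = "kmer", k = 2)
  expect_equal(dim(wide), c(2, 1 + canonical_kmer_dim(2)))
  expect_equal(wide$genome, c("g1", "g2"))
  expect_equal(unname(rowSums(as.matrix(wide[, -1]))), c(1, 1), tolerance = 1e-9)
  # columns are the canonical representatives in lexicographic order
  expect_equal(names(wide)[-1], sort(names(wide)[-1]))
  expect_equal(wide[["AA"]][1], canonical_kmer_profile(recs$seq[1], 2)$freq[1])
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, path, progress = FALSE)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(wide))
})

test_that("composition scores favour the compositionally matching host", {
  set.seed(55)
  # host A rich in GC, host B rich in AT; phage is a substring of host A
  hostA <- paste(sample(c("G", "C", "A", "T"), 8000, TRUE, prob = c(.4, .4, .1, .1)), collapse = "")
  hostB <- paste(sample(c("G", "C", "A", "T"), 8000, TRUE, prob = c(.1, .1, .4, .4)), collapse = "")
  phage <- substring(hostA, 2001, 5000)
  tbl <- composition_scores(seq_tbl("p", phage), seq_tbl(c("A", "B"), c(hostA, hostB)),
                            kind = "kmer", k = 4)
  expect_equal(nrow(tbl), 2)
  expect_false(attr(tbl, "higher_is_better"))
  expect_equal(top_hosts(tbl, "p"), "A")
  # pearson variant flips orientation
  tblp <- composition_scores(seq_tbl("p", phage), seq_tbl(c("A", "B"), c(hostA, hostB)),
                             kind = "kmer", k = 4, metric = "pearson")
  expect_true(attr(tblp, "higher_is_better"))
  expect_equal(top_hosts(tblp, "p"), "A")
  # records failing profile computation are dropped with a warning
  expect_warning(
    composition_scores(seq_tbl(c("p", "q"), c(phage, strrep("N", 100))),
                       seq_tbl(c("A", "B"), c(hostA, hostB)), kind = "kmer", k = 4),
    "dropped"
  )
})
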