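test_that("seed index retrieves every occurrence and agrees with a naive scan", {
  # host of 30 A's: the all-A 15-mer occurs at 16 positions
  idx <- build_seed_index(seq_tbl("h", strrep("A", 30)))
  code_a <- phagehost:::kmer_codes(strrep("A", 15), 15)
  expect_equal(phagehost:::lookup_seed(idx, "h", code_a), 1:16)
  # absent seed
  code_g <- phagehost:::kmer_codes(strrep("G", 15), 15)
  expect_length(phagehost:::lookup_seed(idx, "h", code_g), 0)
  # naive substring-scan oracle on random (seed, host) pairs
  set.seed(61)
  for (i in 1:20) {
    host <- rand_seq(400)
    seed <- if (i %% 2 == 0) substring(host, 100, 114) else rand_seq(15)
    idx <- build_seed_index(seq_tbl("h", host), both_strands = FALSE)
    naive <- which(vapply(1:(nchar(host) - 14),
                          function(p) substring(host, p, p + 14) == seed,
                          logical(1)))
    got <- phagehost:::lookup_seed(idx, "h", phagehost:::kmer_codes(seed, 15))
    expect_equal(got, naive)
  }
})

test_that("longest exact match recovers planted matches on either strand", {
  set.seed(62)
  host <- rand_seq(8000)
  # full phage-in-host prophage case
  phage <- substring(host, 2001, 7000)
  idx <- build_seed_index(seq_tbl("h", host))
  m <- longest_exact_match(phage, "h", idx)
  expect_equal(m$length, 5000)
  expect_equal(m$strand, 1)
  expect_equal(m$host_pos, 2000)
  # single 20 bp island (chance flank extension can lengthen it slightly,
  # so the reference is the independent LCS oracle)
  island <- rand_seq(20)
  p2 <- paste0(rand_seq(1000), island, rand_seq(1000))
  h2 <- paste0(rand_seq(3000), island, rand_seq(3000))
  idx2 <- build_seed_index(seq_tbl("h2", h2))
  m2 <- longest_exact_match(p2, "h2", idx2)
  expect_equal(m2$length, lcs_both_strands(p2, h2))
  expect_gte(m2$length, 20)
  expect_lt(m2$length, 30)
  expect_equal(substring(p2, m2$phage_pos + 1, m2$phage_pos + m2$length),
               substring(h2, m2$host_pos + 1, m2$host_pos + m2$length))
  # reverse-strand planted island
  h3 <- paste0(rand_seq(3000), reverse_complement(island), rand_seq(3000))
  idx3 <- build_seed_index(seq_tbl("h3", h3))
  m3 <- longest_exact_match(p2, "h3", idx3)
  expect_equal(m3$length, lcs_both_strands(p2, h3))
  expect_gte(m3$length, 20)
  expect_equal(m3$strand, -1)
  expect_equal(
    substring(p2, m3$phage_pos + 1, m3$phage_pos + m3$length),
    reverse_complement(substring(h3, m3$host_pos + 1, m3$host_pos + m3$length))
  )
  # 14 bp island only -> no match reported
  isl14 <- rand_seq(14)
  p4 <- paste0(rand_seq(500), isl14, rand_seq(500))
  h4 <- paste0(rand_seq(1500), isl14, rand_seq(1500))
  if (lcs_both_strands(p4, h4) < 15) {
    expect_equal(nrow(longest_exact_match(p4, "h4", build_seed_index(seq_tbl("h4", h4)))), 0)
  }
})

test_that("exact match equals the brute-force LCS oracle and is content-symmetric", {
  set.seed(63)
  for (i in 1:15) {
    plant <- sample(c(0, 10, 14, 15, 16, 25, 60, 150), 1)
    a <- rand_seq(sample(800:2000, 1))
    b <- rand_seq(sample(800:2000, 1))
    if (plant > 0) {
      seg <- rand_seq(plant)
      a <- phagehost:::insert_at(a, seg, sample(nchar(a) - 1, 1))
      seg2 <- if (i %% 3 == 0) reverse_complement(seg) else seg
      b <- phagehost:::insert_at(b, seg2, sample(nchar(b) - 1, 1))
    }
    oracle <- lcs_both_strands(a, b)
    idx <- build_seed_index(seq_tbl("b", b))
    m <- longest_exact_match(a, "b", idx)
    if (oracle >= 15) {
      expect_equal(m$length, oracle)
      # content symmetry: swap roles
      m_swap <- longest_exact_match(b, "a", build_seed_index(seq_tbl("a", a)))
      expect_equal(m_swap$length, oracle)
    } else {
      expect_equal(nrow(m), 0)
    }
  }
})

test_that("exact-match score tables keep ties and respect monotonicity", {
  set.seed(64)
  seg <- rand_seq(40)
  phage <- paste0(rand_seq(400), seg, rand_seq(400))
  hostA <- paste0(rand_seq(900), seg, rand_seq(900))   # same 40 bp
  hostB <- paste0(rand_seq(900), seg, rand_seq(900))   # tied
  hostC <- rand_seq(1800)
  hosts <- seq_tbl(c("A", "B", "C"), c(hostA, hostB, hostC))
  tbl <- exact_match_scores(seq_tbl("p", phage), hosts)
  expect_true(attr(tbl, "higher_is_better"))
  expect_setequal(top_hosts(tbl, "p"), c("A", "B"))
  # implanting a longer identical segment never decreases the score
  seg2 <- rand_seq(80)
  hostA2 <- phagehost:::insert_at(hostA, substring(phage, 100, 179), 200)
  tbl2 <- exact_match_scores(seq_tbl("p", phage), seq_tbl("A", hostA2))
  expect_gte(tbl2$score[1], tbl$score[tbl$host == "A"])
  # host containing the full phage attains the row maximum
  hostD <- paste0(rand_seq(200), phage, rand_seq(200))
  tbl3 <- exact_match_scores(seq_tbl("p", phage),
                             seq_tbl(c("A", "D"), c(hostA, hostD)))
  expect_equal(top_hosts(tbl3, "p"), "D")
  expect_equal(max(tbl3$score), nchar(phage))
})

test_that("matches containing N are not reported", {
  set.seed(65)
  core <- rand_seq(40)
  withN <- paste0(substring(core, 1, 20), "N", substring(core, 22, 40))
  phage <- paste0(rand_seq(300), core, rand_seq(300))
  host <- paste0(rand_seq(300), withN, rand_seq(300))
  idx <- build_seed_index(seq_tbl("h", host))
  m <- longest_exact_match(phage, "h", idx)
  # the best match must stop at the N (clean flanks are 20 and 19 bp, plus
  # possible chance extension into the random flank)
  expect_lt(m$length, 40)
  matched_host <- substring(host, m$host_pos + 1, m$host_pos + m$length)
  matched_phage <- substring(phage, m$phage_pos + 1, m$phage_pos + m$length)
  expect_false(grepl("N", matched_host))
  expect_equal(matched_phage,
               if (m$strand == 1) matched_host else reverse_complement(matched_host))
})

test_that("unrelated random sequences score at chance level only", {
  set.seed(66)
  # 5 kb x 5 kb: expected shared 15-mers ~ 5e3 * 5e3 * 2 / 4^15 ~ 0.05,
  # so almost every replicate scores 0
  zeros <- vapply(1:10, function(i) {
    exact_match_scores(seq_tbl("p", rand_seq(5000)),
                       seq_tbl("h", rand_seq(5000)))$score
  }, numeric(1))
  expect_gte(sum(zeros == 0), 8)
  # 50 kb x 50 kb: a handful of chance 15-16 bp seeds are expected, but
  # nothing approaching a biological match
  tbl <- exact_match_scores(seq_tbl("p", rand_seq(50000)),
                            seq_tbl("h", rand_seq(50000)))
  expect_lt(tbl$score, 30)
})
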