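test_that("fixture config validates fields and rejects unknown ones", {
  cfg <- fixture_config(n_hosts = 4, seed = 3)
  expect_s3_class(cfg, "ph_fixture_config")
  expect_equal(cfg$n_hosts, 4)
  expect_error(fixture_config(nonsense = 1), "unknown config")
  expect_error(fixture_config(bias_strength = 2))
})

test_that("host backgrounds are compositionally separable at full bias, not at zero", {
  set.seed(111)
  cfg1 <- fixture_config(n_hosts = 6, host_len = 8000, bias_strength = 1)
  hs1 <- make_hosts(cfg1)
  expect_true(phagehost:::lineages_tree_consistent(hs1$lineages))
  # split each host genome in half: self-distance (between halves of the
  # same host) should be below cross-host distance for almost all pairs
  halves <- function(s) c(substring(s, 1, nchar(s) / 2), substring(s, nchar(s) / 2 + 1))
  prof <- function(s) canonical_kmer_profile(s, 4)$freq
  P <- lapply(hs1$hosts$seq, function(s) lapply(halves(s), prof))
  d <- function(x, y) sqrt(sum((x - y)^2))
  self_d <- vapply(P, function(h) d(h[[1]], h[[2]]), numeric(1))
  cross <- c()
  for (i in 1:5) for (j in (i + 1):6) cross <- c(cross, d(P[[i]][[1]], P[[j]][[1]]))
  expect_gte(mean(outer(self_d, cross, "<")), 0.95)
  # zero bias: hosts indistinguishable (distance distributions overlap)
  set.seed(112)
  hs0 <- make_hosts(fixture_config(n_hosts = 6, host_len = 8000, bias_strength = 0))
  P0 <- lapply(hs0$hosts$seq, function(s) lapply(halves(s), prof))
  self0 <- vapply(P0, function(h) d(h[[1]], h[[2]]), numeric(1))
  cross0 <- c()
  for (i in 1:5) for (j in (i + 1):6) cross0 <- c(cross0, d(P0[[i]][[1]], P0[[j]][[1]]))
  expect_lt(mean(outer(self0, cross0, "<")), 0.9)
})

test_that("each planting mode leaves its intended trace", {
  set.seed(113)
  cfg <- fixture_config(n_hosts = 2, host_len = 12000, phage_len = 5000, seed = 5)
  host <- rand_seq(12000)
  tr <- phagehost:::random_transition(1)
  # prophage: full phage copied into host
  pro <- make_phage("p", host, tr, "prophage", cfg)
  expect_equal(nchar(pro$host_seq), 12000 + 5000)
  idx <- build_seed_index(seq_tbl("h", pro$host_seq))
  expect_equal(longest_exact_match(pro$phage_seq, "h", idx)$length, 5000)
  # shared gene: diverged copy in phage, intact copy in host
  sg <- make_phage("p", host, tr, "shared_gene", cfg)
  s <- nucleotide_homology(sg$phage_seq, sg$host_seq)
  expect_gte(s$total_aligned_len, 0.5 * cfg$gene_len)
  # spacer donor: array inserted, spacers derived from the phage
  sd <- make_phage("p", host, tr, "spacer_donor", cfg)
  arr <- detect_crispr_arrays(sd$host_seq, "h")
  expect_equal(nrow(arr), 1)
  expect_equal(arr$spacers[[1]], sd$spacers)
  hits <- match_spacers(host_spacers(seq_tbl("h", sd$host_seq)), sd$phage_seq, "p")
  best <- hits[hits$is_best, ]
  expect_equal(sort(best$mismatches), sort(rep(cfg$spacer_mismatches,
                                               length.out = cfg$spacers_per_array)))
  # composition only: sequences unrelated at the exact-match level
  co <- make_phage("p", host, tr, "composition_only", cfg)
  expect_equal(nchar(co$host_seq), nchar(host))
  expect_equal(
    nrow(longest_exact_match(co$phage_seq, "h",
                             build_seed_index(seq_tbl("h", co$host_seq)))), 0)
  expect_error(make_phage("p", host, tr, "warp_drive", cfg), "unknown mode")
})

test_that("abundance simulation couples phages to hosts and honours the overlap rule", {
  set.seed(114)
  cfg <- fixture_config(n_hosts = 3, n_samples = 12, coupling = 1,
                        log_sd = 1, phage_dropout = 0, presence_prob = 1)
  truth <- tibble::tibble(phage = "p1", host = "h1", mode = "abundance_only")
  ab <- simulate_abundance(truth, c("h1", "h2", "h3"), cfg)
  # coupling 1, no dropout, full presence -> correlation exactly 1
  expect_equal(pair_correlation(as.numeric(ab$phage_ab[1, -1]),
                                as.numeric(ab$host_ab[1, -1])), 1)
  # only 6 shared non-zero samples -> no evidence
  x <- c(rexp(6) + 1, rep(0, 6))
  y <- c(rexp(12) + 1)
  expect_true(is.na(pair_correlation(x, y)))
})

test_that("benchmark bundles are deterministic under the master seed", {
  cfg <- fixture_config(n_hosts = 4, host_len = 3000, n_phages = 4,
                        phage_len = 1200, n_samples = 10, seed = 77)
  b1 <- build_benchmark(cfg)
  b2 <- build_benchmark(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  write_benchmark(b1, d1); write_benchmark(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # different seed: different sequences, same schema
  b3 <- build_benchmark(fixture_config(n_hosts = 4, host_len = 3000,
                                       n_phages = 4, phage_len = 1200,
                                       n_samples = 10, seed = 78))
  write_benchmark(b3, d3)
  expect_equal(sort(list.files(d1)), sort(list.files(d3)))
  expect_false(identical(b1$hosts$seq, b3$hosts$seq))
  expect_equal(b1$truth$mode, b3$truth$mode)
})

test_that("written bundles are readable by the module readers", {
  b <- small_benchmark()
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  hosts <- read_fasta(file.path(dir, "hosts.fasta"))
  expect_equal(hosts$seq, b$hosts$seq)
  phages <- read_fasta(file.path(dir, "phages.fasta"))
  expect_equal(phages$id, b$phages$id)
  sp <- read_spacer_fasta(file.path(dir, "spacers.fasta"))
  expect_equal(sp$seq, b$spacers$seq)
  expect_equal(sp$host_id, b$spacers$host_id)
  lin <- read_lineage_table(file.path(dir, "lineages.tsv"))
  expect_equal(lin$taxon, b$lineages$taxon)
  ab <- read_abundance_tsv(file.path(dir, "phage_abundance.tsv"))
  expect_equal(ab$genome, b$phage_ab$genome)
  expect_true(phagehost:::lineages_tree_consistent(lin))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$config$seed, 42)
  # every phage has exactly one true host
  expect_equal(anyDuplicated(b$truth$phage), 0)
  expect_true(all(b$truth$host %in% b$hosts$id))
})
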