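mk_table <- function(S, signal = "test", higher = TRUE) {
  phagehost:::score_table_from_matrix(S, signal, higher)
}

test_that("top_hosts honours ties, orientation, and no-evidence rows", {
  S <- rbind(p1 = c(a = 3, b = 1, c = 3), p2 = c(a = 1, b = 9, c = 2),
             p3 = c(a = NA, b = NA, c = NA))
  tbl <- mk_table(S)
  expect_setequal(top_hosts(tbl, "p1"), c("a", "c"))
  expect_equal(top_hosts(tbl, "p2"), "b")
  expect_length(top_hosts(tbl, "p3"), 0)
  expect_error(top_hosts(tbl, "nope"), "unknown phage")
  low <- mk_table(S, higher = FALSE)
  expect_equal(top_hosts(low, "p1"), "b")
})

test_that("rank accuracy follows the ties-count-as-correct rule with a degeneracy guard", {
  lin <- toy_lineage_tbl(c("a", "b", "c", "d"))
  truth <- tibble::tibble(phage = c("p1", "p2"), host = c("a", "c"))
  # true host is always the unique optimum -> 1.0 at all ranks
  S <- rbind(p1 = c(a = 9, b = 1, c = 1, d = 1), p2 = c(a = 1, b = 1, c = 9, d = 1))
  acc <- accuracy_at_rank(mk_table(S), truth, lin)
  expect_equal(acc$accuracy, rep(1, 6))
  expect_equal(acc$mean_set_size, rep(1, 6))
  # all-tied table: trivially correct at species, exposed by the set size
  Sflat <- rbind(p1 = c(a = 1, b = 1, c = 1, d = 1), p2 = c(a = 1, b = 1, c = 1, d = 1))
  accf <- accuracy_at_rank(mk_table(Sflat), truth, lin)
  expect_equal(accf$accuracy[accf$rank == "species"], 1)
  expect_equal(accf$mean_set_size, rep(4, 6))
  # enlarging a tied optimum set can only increase accuracy
  Swrong <- rbind(p1 = c(a = 1, b = 9, c = 1, d = 1), p2 = c(a = 1, b = 1, c = 9, d = 1))
  Stied <- rbind(p1 = c(a = 9, b = 9, c = 1, d = 1), p2 = c(a = 1, b = 1, c = 9, d = 1))
  expect_gte(
    accuracy_at_rank(mk_table(Stied), truth, lin, "species")$accuracy,
    accuracy_at_rank(mk_table(Swrong), truth, lin, "species")$accuracy
  )
  # accuracy is non-decreasing with rank on tree-structured lineages
  set.seed(101)
  Srand <- matrix(runif(2 * 4), 2, 4, dimnames = list(c("p1", "p2"), c("a", "b", "c", "d")))
  accr <- accuracy_at_rank(mk_table(Srand), truth, lin)
  ord <- match(c("species", "genus", "family", "order", "class", "phylum"), accr$rank)
  expect_true(all(diff(accr$accuracy[ord]) >= -1e-12))
  # phage missing from truth -> error
  expect_error(accuracy_at_rank(mk_table(S), truth[1, ], lin), "missing from truth")
})

test_that("random unique-top-1 species accuracy approaches 1/H", {
  set.seed(102)
  H <- 20
  ids <- paste0("h", 1:H)
  lin <- toy_lineage_tbl(ids)
  n_phage <- 400
  truth <- tibble::tibble(phage = paste0("p", 1:n_phage),
                          host = sample(ids, n_phage, TRUE))
  S <- matrix(runif(n_phage * H), n_phage, H,
              dimnames = list(truth$phage, ids))
  acc <- accuracy_at_rank(mk_table(S), truth, lin, "species")$accuracy
  se <- sqrt((1 / H) * (1 - 1 / H) / n_phage)
  expect_lt(abs(acc - 1 / H), 4 * se)
})

test_that("ROC curves satisfy the endpoint, monotonicity and reflection contracts", {
  # perfect separation: passes through (0,1), AUC = 1
  d <- tibble::tibble(score = c(5, 4, 3, 2, 1), label = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  roc <- roc_curve(d)
  expect_equal(roc$fp_rate[1], 0); expect_equal(roc$tp_rate[1], 0)
  expect_equal(roc$fp_rate[nrow(roc)], 1); expect_equal(roc$tp_rate[nrow(roc)], 1)
  expect_true(any(roc$fp_rate == 0 & roc$tp_rate == 1))
  expect_equal(attr(roc, "auc"), 1)
  expect_true(all(diff(roc$fp_rate) >= 0))
  expect_true(all(diff(roc$tp_rate) >= 0))
  # equal scores enter together
  tied <- tibble::tibble(score = c(2, 2, 1), label = c(TRUE, FALSE, FALSE))
  roct <- roc_curve(tied)
  expect_equal(nrow(roct), 3)  # origin + 2 distinct thresholds
  # orientation flip reflects the curve through the diagonal
  rocf <- roc_curve(d, higher_is_better = FALSE)
  expect_equal(attr(rocf, "auc"), 0)
  # AUC invariant under strictly monotone transforms
  d2 <- dplyr::mutate(d, score = exp(score))
  expect_equal(attr(roc_curve(d2), "auc"), attr(roc_curve(d), "auc"))
  # single-class input -> error; NA scores excluded
  expect_error(roc_curve(tibble::tibble(score = 1:3, label = rep(TRUE, 3))),
               "true and one false")
  withna <- tibble::tibble(score = c(5, NA, 1), label = c(TRUE, TRUE, FALSE))
  expect_equal(attr(roc_curve(withna), "auc"), 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(104)
  for (i in 1:5) {
    n <- 200
    lab <- runif(n) < 0.4
    score <- rnorm(n, mean = ifelse(lab, 0.5 * i / 5, 0))
    ours <- attr(roc_curve(tibble::tibble(score = score, label = lab)), "auc")
    ref <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("random baseline brackets the closed-form expectation k/H", {
  set.seed(103)
  H <- 20
  hosts <- paste0("h", 1:H)
  truth <- tibble::tibble(phage = paste0("p", 1:50), host = sample(hosts, 50, TRUE))
  # pool of 1 host -> accuracy always 1
  t1 <- tibble::tibble(phage = "p1", host = "only")
  expect_equal(random_baseline(t1, "only", hosts_per_phage = 1, n_reps = 5)$accuracy,
               rep(1, 5))
  bl <- random_baseline(truth, hosts, hosts_per_phage = 1:4, n_reps = 400)
  expect_equal(attr(bl, "expectation"), 2.5 / H)
  expect_equal(mean(bl$accuracy), 2.5 / H, tolerance = 0.15)
  expect_error(random_baseline(truth, hosts, hosts_per_phage = 1:30, n_reps = 2),
               "pool")
})

test_that("score tables survive the TSV round trip with a distinct no-evidence marker", {
  S <- rbind(p1 = c(a = 1.5, b = NA), p2 = c(a = 0, b = 2))
  tbl <- mk_table(S, signal = "demo")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path, na = "no_evidence", progress = FALSE)
  txt <- readLines(path)
  expect_true(any(grepl("no_evidence", txt)))
  back <- readr::read_tsv(path, na = "no_evidence", show_col_types = FALSE)
  expect_equal(back$score, tbl$score)
})
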