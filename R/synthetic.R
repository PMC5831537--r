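# Synthetic benchmark with planted ground truth. Each host genome is drawn
# from its own dinucleotide (first-order Markov) background so composition
# is learnable; phages are planted with one mechanism each: an integrated
# prophage copy, a shared gene at configurable divergence, acquired CRISPR
# spacers, composition ameliorated towards the host, or coupled abundances
# only. Hosts are grouped so that both phages of a host carry the same
# mechanism, keeping the mechanisms' genomic side effects separated.

PLANT_MODES <- c("prophage", "shared_gene", "spacer_donor",
                 "composition_only", "abundance_only")

#' Synthetic benchmark configuration
#'
#' Defaults give a benchmark that exercises every signal at desk scale:
#' 30 hosts of 50 kb grouped into a balanced toy taxonomy, 60 phages of
#' 20 kb (two per host, one mechanism per host group). See the package
#' vignette for the rationale behind each default.
#'
#' @param ... Named overrides of the defaults.
#' @return A `ph_fixture_config` list.
#' @export
fixture_config <- function(...) {
  cfg <- list(
    n_hosts = 30L, host_len = 50000L, n_phages = 60L, phage_len = 20000L,
    bias_strength = 1,          # dinucleotide bias of host backgrounds, 0..1
    amelioration = 1,           # pull of composition-only phages to host, 0..1
    gene_len = 900L,            # shared gene length (codon-structured)
    gene_divergence = 0.1,      # per-base substitution rate of the phage copy
    repeat_len = 28L, spacer_len = 32L, spacers_per_array = 3L,
    spacer_mismatches = c(0L, 1L, 2L),  # recycled over planted spacers
    decoy_array_fraction = 0.3, # non-donor hosts given random-spacer arrays
    n_samples = 40L, coupling = 0.9, background_coupling = 0.3,
    presence_prob = 0.6, phage_dropout = 0.1, log_sd = 1,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
  cfg <- utils::modifyList(cfg, over)
  stopifnot(
    cfg$n_hosts > 0, cfg$host_len > 0, cfg$n_phages > 0, cfg$phage_len > 0,
    cfg$bias_strength >= 0, cfg$bias_strength <= 1,
    cfg$amelioration >= 0, cfg$amelioration <= 1,
    cfg$gene_divergence >= 0, cfg$gene_divergence <= 1,
    cfg$decoy_array_fraction >= 0, cfg$decoy_array_fraction <= 1,
    cfg$coupling >= 0, cfg$coupling <= 1
  )
  structure(cfg, class = "ph_fixture_config")
}

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# first-order Markov transition matrix: uniform blended with a random
# host-specific matrix by `bias` in [0, 1]
random_transition <- function(bias) {
  D <- matrix(runif(16)^2, 4, 4)
  D <- D / rowSums(D)
  (1 - bias) * 0.25 + bias * D
}

markov_seq <- function(n, trans) {
  cum <- t(apply(trans, 1, cumsum))
  u <- runif(n)
  idx <- integer(n)
  cur <- sample.int(4, 1)
  for (i in seq_len(n)) {
    cur <- findInterval(u[i], cum[cur, ]) + 1L
    idx[i] <- cur
  }
  paste(BASES[idx], collapse = "")
}

# substitute exactly n_sub positions (to a different base)
mutate_n <- function(s, n_sub) {
  if (n_sub == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  pos <- sample.int(length(ch), n_sub)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), character(1))
  paste(ch, collapse = "")
}

# substitute each position independently with probability `rate`
mutate_rate <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1), character(1))
  paste(ch, collapse = "")
}

# codon-structured gene: start codon, stop-free body, stop codon
make_gene <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  codons <- Biostrings::mkAllStrings(BASES, 3)
  body <- sample(setdiff(codons, STOP_CODONS), len / 3 - 2, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

insert_at <- function(s, insert, pos) {
  # insert after `pos` characters (0 <= pos <= nchar(s))
  paste0(substring(s, 1, pos), insert, substring(s, pos + 1, nchar(s)))
}

# CRISPR array string from a repeat and spacer set: R S1 R S2 ... R
array_string <- function(repeat_seq, spacers) {
  paste0(paste0(repeat_seq, spacers, collapse = ""), repeat_seq)
}

# planted arrays must have unambiguous repeat boundaries: if all spacers
# started (or ended) with the same base, that conserved column would
# rightly be absorbed into the repeat by any boundary-growing detector
spacer_boundaries_ok <- function(spacers) {
  length(unique(substring(spacers, 1, 1))) > 1 &&
    length(unique(substring(spacers, nchar(spacers), nchar(spacers)))) > 1
}

# balanced toy taxonomy over host ids: ranks group hosts by powers of two
toy_lineages <- function(host_ids) {
  i <- seq_along(host_ids)
  grp <- function(width, prefix) sprintf("%s%02d", prefix, ceiling(i / width))
  tibble(
    taxon = host_ids,
    species = sprintf("s%02d", i),
    genus = grp(2, "g"), family = grp(4, "f"), order = grp(8, "o"),
    class = grp(16, "c"), phylum = grp(32, "p")
  )
}

#' Generate host genomes and their toy taxonomy
#'
#' Each host is drawn from its own dinucleotide-biased background
#' (`bias_strength` blends a host-specific random transition matrix with
#' the uniform one), and hosts are grouped into a balanced tree of genera,
#' families, orders, classes and phyla.
#'
#' @param config A [fixture_config()].
#' @return List with `hosts` (sequence tibble), `lineages` (lineage
#'   tibble) and `transitions` (per-host Markov matrices).
#' @export
make_hosts <- function(config) {
  ids <- sprintf("host%03d", seq_len(config$n_hosts))
  trans <- purrr::map(ids, ~ random_transition(config$bias_strength))
  seqs <- vapply(trans, function(tr) markov_seq(config$host_len, tr), character(1))
  list(
    hosts = seq_tbl(ids, seqs),
    lineages = toy_lineages(ids),
    transitions = setNames(trans, ids)
  )
}

#' Plant one phage for a host
#'
#' Generates a phage genome and applies the side effects of the planted
#' mechanism to the host sequence: `prophage` copies the full phage into
#' the host; `shared_gene` puts a codon-structured gene into the host and a
#' diverged copy into the phage; `spacer_donor` inserts a CRISPR array into
#' the host whose spacers are phage substrings with the configured
#' mismatches; `composition_only` samples the phage from the host's
#' composition model blended with uniform by `amelioration`;
#' `abundance_only` leaves the sequences unrelated.
#'
#' @param phage_id Identifier of the new phage.
#' @param host_seq Current host sequence.
#' @param host_trans The host's Markov transition matrix.
#' @param mode One of `r paste0('"', PLANT_MODES, '"', collapse = ", ")`.
#' @param config A [fixture_config()].
#' @param avoid Optional two-column matrix of 1-based host intervals that
#'   an inserted CRISPR array must not split (earlier arrays in the same
#'   host).
#' @return List `phage_seq`, `host_seq` (possibly modified), `spacers`
#'   (planted spacer sequences, or `NULL`), `insert_span` (1-based host
#'   span of an inserted array, or `NULL`).
#' @export
make_phage <- function(phage_id, host_seq, host_trans, mode, config,
                       avoid = NULL) {
  if (!mode %in% PLANT_MODES) abort(sprintf("unknown mode '%s'", mode))
  n <- config$phage_len
  spacers <- NULL
  insert_span <- NULL
  phage_seq <- switch(mode,
    composition_only = {
      tr <- (1 - config$amelioration) * 0.25 + config$amelioration * host_trans
      markov_seq(n, tr)
    },
    random_seq(n)
  )
  if (mode == "prophage") {
    host_seq <- insert_at(host_seq, phage_seq,
                          sample.int(nchar(host_seq) - 1, 1))
  } else if (mode == "shared_gene") {
    gene <- make_gene(config$gene_len)
    host_seq <- insert_at(host_seq, gene, sample.int(nchar(host_seq) - 1, 1))
    phage_seq <- insert_at(phage_seq, mutate_rate(gene, config$gene_divergence),
                           sample.int(n - 1, 1))
  } else if (mode == "spacer_donor") {
    k <- config$spacers_per_array
    mm <- rep(config$spacer_mismatches, length.out = k)
    repeat {
      starts <- sort(sample.int(n - config$spacer_len, k))
      if (any(diff(starts) < config$spacer_len)) next  # overlapping protospacers
      proto <- substring(phage_seq, starts, starts + config$spacer_len - 1)
      spacers <- vapply(seq_len(k), function(i) mutate_n(proto[i], mm[i]),
                        character(1))
      if (spacer_boundaries_ok(spacers)) break
    }
    arr <- array_string(random_seq(config$repeat_len), spacers)
    pos <- sample_insert_pos(nchar(host_seq), avoid)
    host_seq <- insert_at(host_seq, arr, pos)
    insert_span <- c(pos + 1L, pos + nchar(arr))
  }
  list(phage_seq = phage_seq, host_seq = host_seq, spacers = spacers,
       insert_span = insert_span)
}

# insertion point (insert after `pos` characters) that does not split any
# interval in `avoid` (two-column matrix of 1-based inclusive spans)
sample_insert_pos <- function(len, avoid = NULL) {
  repeat {
    pos <- sample.int(len - 1, 1)
    if (is.null(avoid) || nrow(avoid) == 0 ||
        !any(pos >= avoid[, 1] - 1 & pos <= avoid[, 2] - 1)) {
      return(pos)
    }
  }
}

#' Simulate coupled abundance matrices
#'
#' Host abundances are log-normal with per-sample Bernoulli presence; the
#' phage's log-abundance follows its true host's with correlation
#' `coupling` (for abundance-only phages) or `background_coupling`
#' (for the rest: phages co-occur with their hosts regardless of the
#' planted genomic mechanism, just more noisily). Phages are absent
#' wherever their host is, plus an independent dropout.
#'
#' @param truth Tibble `phage`, `host`, `mode`.
#' @param host_ids All host ids.
#' @param config A [fixture_config()].
#' @return List of abundance tibbles `phage_ab`, `host_ab`.
#' @export
simulate_abundance <- function(truth, host_ids, config) {
  S <- config$n_samples
  sample_ids <- sprintf("sample%02d", seq_len(S))
  host_state <- purrr::map(host_ids, function(h) {
    list(mu = rnorm(1, 0, 1), z = rnorm(S),
         present = runif(S) < config$presence_prob)
  })
  names(host_state) <- host_ids
  host_mat <- t(vapply(host_state, function(st) {
    ifelse(st$present, exp(st$mu + config$log_sd * st$z), 0)
  }, numeric(S)))
  phage_mat <- t(vapply(seq_len(nrow(truth)), function(i) {
    st <- host_state[[truth$host[i]]]
    cc <- if (truth$mode[i] == "abundance_only") config$coupling else config$background_coupling
    zp <- cc * st$z + sqrt(1 - cc^2) * rnorm(S)
    present <- st$present & runif(S) >= config$phage_dropout
    ifelse(present, exp(st$mu + config$log_sd * zp), 0)
  }, numeric(S)))
  list(
    phage_ab = bind_cols(tibble(genome = truth$phage),
                         as_tibble(`colnames<-`(phage_mat, sample_ids))),
    host_ab = bind_cols(tibble(genome = host_ids),
                        as_tibble(`colnames<-`(host_mat, sample_ids)))
  )
}

#' Build the full synthetic benchmark
#'
#' Deterministic under `config$seed`: hosts with distinct compositional
#' backgrounds, phages planted with one mechanism per host group (two
#' phages per host), decoy CRISPR arrays with random spacers in a fraction
#' of non-donor hosts, coupled abundance matrices, a tree-consistent
#' lineage table and the phage-to-host truth with the planted mode.
#'
#' @param config A [fixture_config()].
#' @return A `ph_benchmark` list: `hosts`, `phages` (sequence tibbles),
#'   `truth` (`phage`, `host`, `mode`), `lineages`, `spacers` (planted,
#'   id `host|array|ordinal`), `phage_ab`, `host_ab`, `config`.
#' @export
build_benchmark <- function(config = fixture_config()) {
  if (!inherits(config, "ph_fixture_config")) config <- do.call(fixture_config, config)
  set.seed(config$seed)
  hs <- make_hosts(config)
  hosts <- hs$hosts
  n_modes <- length(PLANT_MODES)
  hosts_per_mode <- ceiling(config$n_hosts / n_modes)
  host_mode <- PLANT_MODES[ceiling(seq_len(config$n_hosts) / hosts_per_mode)]
  phage_ids <- sprintf("phage%03d", seq_len(config$n_phages))
  phage_host_idx <- ((seq_len(config$n_phages) - 1) %% config$n_hosts) + 1
  phage_seqs <- character(config$n_phages)
  planted_spacers <- list()
  array_spans <- purrr::map(seq_len(config$n_hosts),
                            ~ matrix(integer(0), ncol = 2))
  for (p in seq_len(config$n_phages)) {
    hi <- phage_host_idx[p]
    res <- make_phage(phage_ids[p], hosts$seq[hi], hs$transitions[[hi]],
                      host_mode[hi], config, avoid = array_spans[[hi]])
    hosts$seq[hi] <- res$host_seq
    phage_seqs[p] <- res$phage_seq
    if (!is.null(res$insert_span)) {
      sp <- array_spans[[hi]]
      # earlier spans downstream of the new insertion shift right
      shift <- sp[, 1] > res$insert_span[1]
      sp[shift, ] <- sp[shift, , drop = FALSE] + diff(res$insert_span) + 1L
      array_spans[[hi]] <- rbind(sp, res$insert_span)
    }
    if (!is.null(res$spacers)) {
      planted_spacers[[length(planted_spacers) + 1]] <-
        tibble(host_id = hosts$id[hi], seqs = list(res$spacers))
    }
  }
  # decoy arrays: random spacers in a fraction of the non-donor hosts
  non_donor <- which(host_mode != "spacer_donor")
  n_decoy <- round(config$decoy_array_fraction * length(non_donor))
  decoy_hosts <- sort(sample(non_donor, n_decoy))
  for (hi in decoy_hosts) {
    repeat {
      sp <- vapply(seq_len(config$spacers_per_array),
                   function(i) random_seq(config$spacer_len), character(1))
      if (spacer_boundaries_ok(sp)) break
    }
    arr <- array_string(random_seq(config$repeat_len), sp)
    hosts$seq[hi] <- insert_at(hosts$seq[hi], arr,
                               sample.int(nchar(hosts$seq[hi]) - 1, 1))
    planted_spacers[[length(planted_spacers) + 1]] <-
      tibble(host_id = hosts$id[hi], seqs = list(sp))
  }
  array_no <- integer(0)  # running array index per host
  spacers <- purrr::map_dfr(planted_spacers, function(row) {
    h <- row$host_id
    array_no[h] <<- (if (h %in% names(array_no)) array_no[[h]] else 0L) + 1L
    sp <- row$seqs[[1]]
    tibble(
      spacer_id = sprintf("%s|%d|%d", h, array_no[[h]], seq_along(sp)),
      host_id = h, array_index = array_no[[h]], ordinal = seq_along(sp),
      seq = sp
    )
  })
  truth <- tibble(
    phage = phage_ids,
    host = hosts$id[phage_host_idx],
    mode = host_mode[phage_host_idx]
  )
  ab <- simulate_abundance(truth, hosts$id, config)
  structure(
    list(
      hosts = hosts, phages = seq_tbl(phage_ids, phage_seqs),
      truth = truth, lineages = hs$lineages, spacers = spacers,
      phage_ab = ab$phage_ab, host_ab = ab$host_ab, config = config
    ),
    class = "ph_benchmark"
  )
}

#' Write a benchmark bundle to disk
#'
#' Emits `hosts.fasta`, `phages.fasta`, `spacers.fasta` (planted spacers),
#' `phage_abundance.tsv`, `host_abundance.tsv`, `lineages.tsv`,
#' `truth.tsv` and `manifest.json` (config plus per-phage planted mode),
#' all readable by the corresponding module readers.
#'
#' @param bench A `ph_benchmark` from [build_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_fasta(bench$hosts, fp("hosts.fasta"))
  write_fasta(bench$phages, fp("phages.fasta"))
  if (nrow(bench$spacers) > 0) write_spacer_fasta(bench$spacers, fp("spacers.fasta"))
  write_abundance_tsv(bench$phage_ab, fp("phage_abundance.tsv"))
  write_abundance_tsv(bench$host_ab, fp("host_abundance.tsv"))
  readr::write_tsv(bench$lineages, fp("lineages.tsv"), progress = FALSE)
  readr::write_tsv(bench$truth, fp("truth.tsv"), progress = FALSE)
  manifest <- list(config = unclass(bench$config),
                   phages = bench$truth)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
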