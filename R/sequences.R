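# Sequence records, reverse complement, ORF calling, translation, FASTA I/O.
#
# A sequence set is an ordinary tibble with columns
#   id   : unique character identifier
#   seq  : nucleotide string over {A,C,G,T,N}
#   cds  : (optional) list-column of tibbles (start, end, strand), 0-based
#          half-open coordinates on the forward strand
#   host : (optional) annotated host taxon name
# so sequence sets compose with dplyr like any other table.

VALID_BASES <- c("A", "C", "G", "T", "N")

# normalize raw input: uppercase, U -> T, then validate the alphabet
clean_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf(
      "invalid alphabet in %s: characters outside {A,C,G,T,N,U} in %d record(s)",
      what, sum(bad)
    ))
  }
  x
}

#' Build a sequence table
#'
#' Constructs the tibble representation of a set of nucleotide sequence
#' records used throughout the package. Sequences are uppercased, `U` is
#' mapped to `T`, and any character outside `{A,C,G,T,N}` is an error.
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of nucleotide sequences.
#' @param host Optional character vector of annotated host taxon names.
#' @param cds Optional list of per-record CDS tables, each a data frame with
#'   columns `start`, `end` (0-based half-open) and `strand` (+1/-1).
#' @return A tibble with columns `id`, `seq` and, when supplied, `host` and
#'   `cds`.
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "ggnn"))
#' @export
seq_tbl <- function(id, seq, host = NULL, cds = NULL) {
  if (anyDuplicated(id)) abort("duplicate sequence ids")
  seq <- clean_seq(seq)
  if (any(nchar(seq) == 0)) abort("empty sequence not allowed")
  out <- tibble(id = as.character(id), seq = seq)
  if (!is.null(host)) out$host <- as.character(host)
  if (!is.null(cds)) {
    stopifnot(length(cds) == nrow(out))
    lens <- nchar(seq)
    for (i in seq_along(cds)) {
      ci <- cds[[i]]
      if (is.null(ci) || nrow(ci) == 0) next
      if (any((ci$end - ci$start) %% 3 != 0)) {
        abort(sprintf("CDS length not divisible by 3 in record '%s'", id[i]))
      }
      if (any(ci$start < 0 | ci$end > lens[i] | ci$start >= ci$end)) {
        abort(sprintf("CDS interval out of bounds in record '%s'", id[i]))
      }
    }
    out$cds <- cds
  }
  out
}

#' Reverse complement
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet; `N` maps to
#' `N`. An involution: `reverse_complement(reverse_complement(x))` is `x`.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("AAAC")
#' @export
reverse_complement <- function(seq) {
  seq <- clean_seq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Read a FASTA file into a sequence table
#'
#' Multi-record FASTA (wrapped or unwrapped, LF or CRLF). Record ids are the
#' header up to the first whitespace. Lowercase bases are uppercased and `U`
#' mapped to `T`; an empty file or duplicated ids are errors.
#'
#' @param path Path to a FASTA file.
#' @return A sequence tibble (see [seq_tbl()]).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) abort(sprintf("duplicate ids in FASTA file: %s", path))
  seq_tbl(ids, unname(as.character(set)))
}

#' Write a sequence table to FASTA
#'
#' @param records A sequence tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wb")  # binary: deterministic bytes across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    s <- records$seq[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    lines <- substring(s, starts, pmin(starts + width - 1L, n))
    writeLines(c(paste0(">", records$id[i]), lines), con, sep = "\n")
  }
  invisible(path)
}

#' Read GenBank-flavored records
#'
#' Minimal ingestion of flat GenBank records, limited to what host
#' annotation needs: the sequence (ORIGIN block), `CDS` feature locations
#' (`start..end` and `complement(start..end)`; joined or fuzzy locations
#' are skipped with a warning) and the `/host="..."` source qualifier.
#' Multi-record files (separated by `//`) are supported.
#'
#' @param path Path to a GenBank flat file.
#' @return A sequence tibble with `id`, `seq`, `host` (NA when absent) and
#'   a `cds` list-column (0-based half-open, strand +1/-1).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, head(lines, -1) == "//")))
  out <- purrr::map_dfr(recs, function(rl) {
    if (!any(grepl("^LOCUS", rl))) return(NULL)
    id <- strsplit(trimws(sub("^LOCUS", "", grep("^LOCUS", rl, value = TRUE)[1])),
                   "\\s+")[[1]][1]
    # sequence: ORIGIN block up to //
    oi <- grep("^ORIGIN", rl)
    seq <- ""
    if (length(oi) == 1) {
      body <- rl[(oi + 1):length(rl)]
      body <- body[!grepl("^//", body)]
      seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    }
    if (nchar(seq) == 0) abort(sprintf("record '%s' has no sequence", id))
    host <- NA_character_
    hq <- grep("/host=\"", rl, value = TRUE)
    if (length(hq) > 0) host <- sub('.*?/host="([^"]*)".*', "\\1", hq[1])
    # CDS feature locations (first line of each feature)
    cds_lines <- trimws(grep("^\\s{5}CDS\\s", rl, value = TRUE))
    loc <- sub("^CDS\\s+", "", cds_lines)
    simple <- grepl("^(complement\\()?<?\\d+\\.\\.>?\\d+\\)?$", loc)
    if (any(!simple)) {
      warn(sprintf("record '%s': %d CDS with join/fuzzy locations skipped",
                   id, sum(!simple)))
    }
    loc <- loc[simple]
    strand <- ifelse(grepl("^complement", loc), -1L, 1L)
    nums <- regmatches(loc, gregexpr("\\d+", loc))
    start1 <- as.integer(vapply(nums, `[`, character(1), 1))
    end1 <- as.integer(vapply(nums, `[`, character(1), 2))
    cds <- tibble(start = start1 - 1L, end = end1, strand = strand)
    # drop CDS that violate the frame/bounds invariants rather than error
    ok <- (cds$end - cds$start) %% 3 == 0 & cds$end <= nchar(seq) & cds$start >= 0
    seq_tbl(id, seq, host = host, cds = list(cds[ok, ]))
  })
  if (nrow(out) == 0) abort(sprintf("no GenBank records in %s", path))
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

# translate in-frame nucleotide strings (lengths divisible by 3); stops = "*"
translate_codons <- function(s) {
  out <- character(length(s))
  ok <- nchar(s) >= 3
  if (any(ok)) {
    out[ok] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(s[ok]),
      if.fuzzy.codon = "X", no.init.codon = TRUE
    ))
  }
  out
}

# scan one forward-strand frame (offset 0..2) for ORFs; returns tibble of
# 0-based half-open coords on the scanned strand
scan_frame <- function(s, offset, min_codons) {
  n <- nchar(s)
  ncod <- (n - offset) %/% 3
  if (ncod < min_codons + 1) {
    return(tibble(start = integer(), end = integer()))
  }
  from <- offset + 1 + 3 * (seq_len(ncod) - 1)
  codons <- substring(s, from, from + 2)
  stops <- which(codons %in% STOP_CODONS)
  starts <- which(codons %in% START_CODONS)
  if (length(stops) == 0 || length(starts) == 0) {
    return(tibble(start = integer(), end = integer()))
  }
  prev <- c(0L, stops[-length(stops)])
  # first start codon strictly after the previous stop and before this stop
  idx <- findInterval(prev, starts) + 1L
  ok <- idx <= length(starts) & starts[pmin(idx, length(starts))] < stops
  st <- starts[idx[ok]]
  sp <- stops[ok]
  keep <- (sp - st) >= min_codons  # peptide codons (stop excluded)
  st <- st[keep]; sp <- sp[keep]
  tibble(
    start = offset + 3L * (st - 1L),        # 0-based
    end   = offset + 3L * sp                # half-open, includes stop codon
  )
}

#' Call open reading frames
#'
#' Scans all six frames for ORFs that begin with a start codon (`ATG`, `GTG`,
#' `TTG`), end at the first in-frame stop, and encode at least `min_codons`
#' amino acids. Coordinates are 0-based half-open on the forward strand; for
#' `strand == -1` they give the forward-strand footprint of the reverse-strand
#' ORF. The default minimum of 60 codons follows common prokaryotic practice.
#'
#' @param seq A single nucleotide string.
#' @param min_codons Minimum peptide length in codons (stop excluded), >= 2.
#' @return Tibble with columns `start`, `end`, `strand`, `peptide`.
#' @examples
#' find_orfs("ATGAAATAA", min_codons = 2)
#' @export
find_orfs <- function(seq, min_codons = 60L) {
  stopifnot(length(seq) == 1, min_codons >= 2)
  seq <- clean_seq(seq)
  n <- nchar(seq)
  rc <- reverse_complement(seq)
  fwd <- purrr::map_dfr(0:2, function(f) scan_frame(seq, f, min_codons))
  rev <- purrr::map_dfr(0:2, function(f) scan_frame(rc, f, min_codons))
  out <- bind_rows(
    if (nrow(fwd)) mutate(fwd, strand = 1L, .seq = substring(seq, start + 1, end)),
    if (nrow(rev)) mutate(rev,
      strand = -1L,
      .seq = substring(rc, start + 1, end),
      start2 = n - end, end = n - start, start = NULL
    ) |> rename(start = "start2")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(
      start = integer(), end = integer(), strand = integer(),
      peptide = character()
    ))
  }
  out$peptide <- sub("\\*$", "", translate_codons(out$.seq))
  out |>
    select("start", "end", "strand", "peptide") |>
    arrange(.data$start, .data$strand)
}

#' Six-frame translation
#'
#' Translates the three forward frames and the three frames of the reverse
#' complement with the standard genetic code; stop codons are rendered `*`
#' and a trailing partial codon is dropped.
#'
#' @param seq A single nucleotide string with at least 3 bases.
#' @return Named character vector of 6 peptides (`F0,F1,F2,R0,R1,R2`);
#'   empty strings when the frame is shorter than one codon.
#' @export
six_frame_translate <- function(seq) {
  stopifnot(length(seq) == 1)
  seq <- clean_seq(seq)
  if (nchar(seq) < 3) {
    return(setNames(rep("", 6), c("F0", "F1", "F2", "R0", "R1", "R2")))
  }
  rc <- reverse_complement(seq)
  one <- function(s, f) {
    n <- nchar(s)
    len <- ((n - f) %/% 3) * 3
    if (len < 3) return("")
    translate_codons(substring(s, f + 1, f + len))
  }
  setNames(
    c(vapply(0:2, one, character(1), s = seq), vapply(0:2, one, character(1), s = rc)),
    c("F0", "F1", "F2", "R0", "R1", "R2")
  )
}

# resolve the coding sequences of one record: annotated CDS when present,
# called ORFs otherwise; returns list(seqs = character(), source = chr)
coding_seqs <- function(seq, cds = NULL, min_codons = 60L) {
  if (!is.null(cds) && nrow(cds) > 0) {
    iv <- cds; source <- "annotated"
  } else {
    iv <- find_orfs(seq, min_codons = min_codons); source <- "orf"
  }
  if (nrow(iv) == 0) return(list(seqs = character(), source = source))
  seqs <- substring(seq, iv$start + 1, iv$end)
  neg <- iv$strand < 0
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  list(seqs = seqs, source = source)
}
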