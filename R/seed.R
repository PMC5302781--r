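#' Extract the 6-mer seed of a mature miRNA
#'
#' The seed is nucleotides 2-7 from the 5' end of the mature sequence; a
#' 6-mer perfect match to its reverse complement is the minimal pairing
#' requirement used for target-site scanning.
#'
#' @param mature_sequence mature miRNA sequence (RNA alphabet; T accepted and
#'   normalised to U), length >= 7.
#' @return The 6-character seed, RNA alphabet.
#' @export
extract_seed <- function(mature_sequence) {
  s <- chartr("T", "U", toupper(mature_sequence))
  if (nchar(s) < 7) {
    abort(sprintf("Mature sequence too short for a 2-7 seed (%d nt < 7).", nchar(s)))
  }
  substr(s, 2L, 7L)
}

#' Convert a seed to its DNA match site
#'
#' The site recorded in a target transcript is the reverse complement of the
#' seed, expressed in the DNA alphabet (A<->U/T, C<->G).
#'
#' @param seed 6-mer seed over `{A, C, G, U}` (T accepted).
#' @return The 6-mer DNA match site.
#' @export
seed_to_site <- function(seed) {
  s <- chartr("T", "U", toupper(seed))
  if (grepl("[^ACGU]", s)) {
    abort(paste0("Seed contains characters outside {A,C,G,U}: ", seed))
  }
  comp <- chartr("ACGU", "TGCA", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Count occurrences of a site in a sequence
#'
#' Counts exact, possibly overlapping occurrences (the scan slides one
#' position at a time). Ambiguity codes such as `N` never match. Sequences
#' shorter than the site yield 0.
#'
#' @param sequence DNA sequence string (`{A,C,G,T}`, possibly `N`).
#' @param site DNA k-mer to count (6-mer in the seed-match setting).
#' @return Integer occurrence count.
#' @export
count_sites <- function(sequence, site) {
  if (nchar(sequence) < nchar(site)) return(0L)
  Biostrings::countPattern(site, Biostrings::BString(sequence), fixed = TRUE)
}

#' Derive seeds and match sites for a table of miRNAs
#'
#' @param mirnas tibble with `mirna_id`, `mature_sequence` (see [read_mirna()]).
#' @return The input with `seed` (RNA) and `match_site` (DNA) columns added.
#' @export
mirna_seeds <- function(mirnas) {
  mirnas %>%
    mutate(
      seed = map_chr(.data$mature_sequence, extract_seed),
      match_site = map_chr(.data$seed, seed_to_site)
    )
}

#' Build the seed-match index
#'
#' Scans every transcript for every miRNA's 6-mer match site and records the
#' occurrence counts together with the number of 6-mer windows each transcript
#' offers (`max(length - 5, 0)`). The window totals define the universe of the
#' hypergeometric enrichment test.
#'
#' @param sequences tibble with `id`, `sequence` (see [read_transcript_fasta()]);
#'   transcript ids must be unique.
#' @param mirnas tibble with `mirna_id` and either `match_site` or
#'   `mature_sequence` (sites are derived if absent).
#' @return An object of class `seed_index`: list with `counts` (tibble
#'   `transcript_id`, `mirna_id`, `count`), `windows` (tibble `transcript_id`,
#'   `windows`), `totals` (tibble `mirna_id`, `total_count`) and `sites`
#'   (tibble `mirna_id`, `match_site`).
#' @export
build_seed_index <- function(sequences, mirnas) {
  if (nrow(sequences) == 0 || nrow(mirnas) == 0) {
    abort("Both sequences and miRNAs must be non-empty.")
  }
  if (anyDuplicated(sequences$id)) {
    abort(paste0(
      "Duplicate transcript ids: ",
      paste(unique(sequences$id[duplicated(sequences$id)]), collapse = ", ")
    ))
  }
  if (!"match_site" %in% names(mirnas)) mirnas <- mirna_seeds(mirnas)
  subject <- Biostrings::DNAStringSet(sequences$sequence)
  counts <- purrr::map(seq_len(nrow(mirnas)), function(i) {
    tibble(
      transcript_id = sequences$id,
      mirna_id = mirnas$mirna_id[i],
      count = Biostrings::vcountPattern(mirnas$match_site[i], subject, fixed = TRUE)
    )
  }) %>% bind_rows()
  windows <- tibble(
    transcript_id = sequences$id,
    windows = pmax(sequences$length - 5L, 0L)
  )
  totals <- counts %>%
    group_by(.data$mirna_id) %>%
    summarise(total_count = sum(.data$count), .groups = "drop")
  structure(
    list(
      counts = counts,
      windows = windows,
      totals = totals,
      sites = mirnas %>% select("mirna_id", "match_site")
    ),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(
    "<seed_index>", nrow(x$windows), "transcripts x",
    nrow(x$totals), "miRNAs;",
    sum(x$counts$count), "site occurrences over",
    sum(x$windows$windows), "windows\n"
  )
  invisible(x)
}

#' Export / import a seed index as TSV
#'
#' The TSV carries one row per (transcript, miRNA) pair with the occurrence
#' count and the transcript's window total, which is sufficient to rebuild the
#' index (match sites are carried in a comment-free side table when present).
#'
#' @param index a `seed_index`.
#' @param path output TSV.
#' @return `path` invisibly.
#' @export
write_seed_index <- function(index, path) {
  stopifnot(inherits(index, "seed_index"))
  out <- index$counts %>%
    left_join(index$windows, by = "transcript_id") %>%
    left_join(index$sites, by = "mirna_id")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_seed_index
#' @export
read_seed_index <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "cciic", progress = FALSE)
  windows <- tbl %>% distinct(.data$transcript_id, .data$windows)
  counts <- tbl %>% select("transcript_id", "mirna_id", "count")
  totals <- counts %>%
    group_by(.data$mirna_id) %>%
    summarise(total_count = sum(.data$count), .groups = "drop")
  sites <- tbl %>% distinct(.data$mirna_id, .data$match_site)
  structure(
    list(counts = counts, windows = windows, totals = totals, sites = sites),
    class = "seed_index"
  )
}
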