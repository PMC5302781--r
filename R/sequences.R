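#' Read transcript sequences from FASTA
#'
#' Sequences are upper-cased and the RNA alphabet is normalised to DNA
#' (`U -> T`), so downstream seed-site scanning works on a single alphabet.
#'
#' @param path FASTA file.
#' @param role stored role label, e.g. `"mRNA-3'UTR"` or `"lncRNA-cDNA"`.
#' @return Tibble with columns `id`, `role`, `sequence`, `length`.
#' @export
read_transcript_fasta <- function(path, role = "mRNA-3'UTR") {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(ss))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    abort(paste0(
      "Empty FASTA record(s): ", paste(ids[empty], collapse = ", ")
    ))
  }
  tibble(id = ids, role = role, sequence = unname(seqs),
         length = unname(nchar(seqs)))
}

#' Read mature miRNA sequences
#'
#' Accepts FASTA or a headerless two-column TSV (`id`, `sequence`). Sequences
#' are stored in the RNA alphabet (T normalised to U) since seeds are defined
#' on the mature miRNA.
#'
#' @param path input file.
#' @param format `"auto"` (sniff a leading `>`), `"fasta"` or `"tsv"`.
#' @return Tibble with columns `mirna_id`, `mature_sequence`.
#' @export
read_mirna <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- toupper(as.character(ss))
  } else {
    tbl <- readr::read_tsv(path, col_names = c("mirna_id", "mature_sequence"),
                           col_types = "cc", progress = FALSE)
    ids <- tbl$mirna_id
    seqs <- toupper(tbl$mature_sequence)
  }
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate miRNA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tibble(mirna_id = ids, mature_sequence = chartr("T", "U", unname(seqs)))
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` features, groups them by `transcript_id`, and converts the
#' 1-based inclusive GTF coordinates to 0-based half-open intervals so that
#' interval length is simply `end - start`. Strand is recorded but sequences
#' are assumed to be supplied sense-strand; no reverse complementing happens
#' here.
#'
#' @param path GTF file with `exon` rows carrying `gene_id` and
#'   `transcript_id` attributes.
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `strand`, `n_exons`, `exonic_length`, and `exons`, a list-column of
#'   two-column matrices (`start`, `end`, 0-based half-open).
#' @export
read_gtf_transcripts <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  line_no <- which(body)
  is_exon <- vapply(fields, function(f) length(f) >= 9 && f[3] == "exon", logical(1))
  if (!any(is_exon)) abort("No exon features found in GTF.")
  fields <- fields[is_exon]
  line_no <- line_no[is_exon]
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  attrs <- vapply(fields, `[`, character(1), 9L)
  tx <- attr_of(attrs, "transcript_id")
  gene <- attr_of(attrs, "gene_id")
  if (anyNA(tx)) {
    abort(paste0(
      "exon feature without transcript_id attribute at line(s): ",
      paste(line_no[is.na(tx)], collapse = ", ")
    ))
  }
  exons <- tibble(
    transcript_id = tx,
    gene_id = gene,
    strand = vapply(fields, `[`, character(1), 7L),
    # GTF is 1-based inclusive; internal representation is 0-based half-open
    start = as.integer(vapply(fields, `[`, character(1), 4L)) - 1L,
    end = as.integer(vapply(fields, `[`, character(1), 5L))
  )
  exons %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = .data$gene_id[1],
      strand = .data$strand[1],
      n_exons = n(),
      exonic_length = sum(.data$end - .data$start),
      exons = list(cbind(start = sort(.data$start),
                         end = .data$end[order(.data$start)])),
      .groups = "drop"
    )
}
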