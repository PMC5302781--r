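# shared fixture builders and independent oracles

make_samples <- function(n, conditions = "normal") {
  patients <- sprintf("P%02d", seq_len(n))
  if (identical(conditions, "both")) {
    tibble::tibble(
      sample_id = c(paste0(patients, "_N"), paste0(patients, "_C")),
      patient_id = rep(patients, 2),
      condition = rep(c("normal", "cancer"), each = n)
    )
  } else {
    tibble::tibble(
      sample_id = paste0(patients, "_S"),
      patient_id = patients,
      condition = conditions
    )
  }
}

make_es <- function(values, role = "mRNA", conditions = "normal") {
  n <- ncol(values)
  samples <- make_samples(if (identical(conditions, "both")) n / 2 else n,
                          conditions)
  colnames(values) <- samples$sample_id
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("%s_%02d", role, seq_len(nrow(values)))
  }
  expression_set(values, samples, role)
}

# brute-force sliding-window substring count (independent of Biostrings)
brute_count <- function(sequence, site) {
  k <- nchar(site)
  L <- nchar(sequence)
  if (L < k) return(0L)
  sum(vapply(seq_len(L - k + 1),
             function(i) substr(sequence, i, i + k - 1) == site,
             logical(1)))
}

# exact hypergeometric upper tail by combinatorial enumeration
brute_hyper_upper <- function(k, N, K, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

write_tiny_gtf <- function(path, transcripts) {
  # transcripts: list of list(tx, gene, exons = list(c(start1based, end1based)))
  lines <- unlist(lapply(transcripts, function(t) {
    vapply(t$exons, function(e) {
      sprintf(
        'chr8\ttest\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s";',
        e[1], e[2], t$gene, t$tx
      )
    }, character(1))
  }))
  writeLines(lines, path)
}
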