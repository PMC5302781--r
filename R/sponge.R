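#' Pearson correlation on pairwise-complete observations
#'
#' @param x,y numeric profiles of equal length; `NA`s are removed pairwise and
#'   at least 3 complete pairs are required.
#' @return The Pearson coefficient, or `NA_real_` (with a warning) when either
#'   profile has zero variance on the complete pairs — an undefined value,
#'   deliberately distinct from 0.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("Profiles must have equal length.")
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) abort("Fewer than 3 complete joint observations.")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance: correlation undefined.")
    return(NA_real_)
  }
  cor(x, y)
}

#' Partial correlation of X and Y given Z
#'
#' First-order partial correlation from the three pairwise Pearson
#' coefficients:
#' \deqn{\rho_{XY|Z} = \frac{\rho_{XY} - \rho_{XZ}\rho_{ZY}}
#'   {\sqrt{1-\rho_{XZ}^2}\,\sqrt{1-\rho_{ZY}^2}}}
#' It equals the correlation of the residuals of the two regressions of X on Z
#' and of Y on Z.
#'
#' @param rho_xy,rho_xz,rho_zy pairwise Pearson correlations.
#' @return The partial correlation, or `NA_real_` (with a warning) when
#'   `|rho_xz|` or `|rho_zy|` is 1.
#' @export
partial_cor <- function(rho_xy, rho_xz, rho_zy) {
  if (anyNA(c(rho_xy, rho_xz, rho_zy))) return(NA_real_)
  if (abs(rho_xz) >= 1 || abs(rho_zy) >= 1) {
    warn("Degenerate conditioning (|rho| = 1): partial correlation undefined.")
    return(NA_real_)
  }
  (rho_xy - rho_xz * rho_zy) / (sqrt(1 - rho_xz^2) * sqrt(1 - rho_zy^2))
}

#' Sensitivity correlation
#'
#' The drop in correlation between two RNA profiles once a miRNA is
#' conditioned away: `S = rho_xy - rho_xy_given_z`. Large S flags the miRNA as
#' the mediator of the co-expression; S near zero means the pair's correlation
#' survives removal of the miRNA and is presumably transcriptional.
#'
#' @param rho_xy Pearson correlation of the pair.
#' @param rho_xy_given_z partial correlation given the miRNA.
#' @return `S`, the exact difference.
#' @export
sensitivity_cor <- function(rho_xy, rho_xy_given_z) {
  rho_xy - rho_xy_given_z
}

#' Select the top-correlated mRNA/lncRNA pairs
#'
#' Computes every mRNA-by-lncRNA Pearson correlation (pairwise-complete) and
#' keeps the pairs whose correlation lies strictly above the given empirical
#' percentile of the full correlation distribution.
#'
#' @param mrna_es,lnc_es [expression_set()]s sharing sample ordering.
#' @param percentile percentile of the overall correlation distribution
#'   (default 99); the induced threshold is reported via `message()`.
#' @return Tibble `x_id`, `y_id`, `rho_xy`, sorted descending by `rho_xy`,
#'   with the induced threshold attached as attribute `"threshold"`.
#' @export
select_top_pairs <- function(mrna_es, lnc_es, percentile = 99) {
  stopifnot(inherits(mrna_es, "expression_set"), inherits(lnc_es, "expression_set"))
  if (!identical(colnames(mrna_es$values), colnames(lnc_es$values))) {
    abort("mRNA and lncRNA sets must share sample ordering.")
  }
  cc <- suppressWarnings(
    cor(t(mrna_es$values), t(lnc_es$values), use = "pairwise.complete.obs")
  )
  vals <- cc[!is.na(cc)]
  if (length(vals) < 100 && percentile == 99) {
    warn("Fewer than 100 pair correlations; the 99th percentile is coarse.")
  }
  thr <- unname(quantile(vals, percentile / 100))
  sel <- which(cc > thr, arr.ind = TRUE)
  inform(sprintf(
    "top-pair selection (> %gth percentile, rho > %.4f): retained %d / %d pairs",
    percentile, thr, nrow(sel), length(vals)
  ))
  out <- tibble(
    x_id = rownames(cc)[sel[, 1]],
    y_id = colnames(cc)[sel[, 2]],
    rho_xy = cc[sel]
  ) %>% arrange(desc(.data$rho_xy))
  attr(out, "threshold") <- thr
  out
}

#' Scan candidate pairs against every miRNA
#'
#' For each selected (mRNA, lncRNA) pair and each miRNA, computes the two
#' miRNA correlations, the partial correlation and the sensitivity
#' correlation S, returning both the full pairs-by-miRNAs S matrix (the
#' heat-map view) and the triplets passing `S > s_threshold`.
#'
#' @param pairs tibble from [select_top_pairs()].
#' @param mrna_es,lnc_es,mirna_es [expression_set()]s sharing sample ordering.
#' @param s_threshold sensitivity threshold (default 0.3, strict `>`).
#' @return List with `s_matrix` (rows `"x_id|y_id"`, columns miRNA ids;
#'   zero-variance miRNAs give `NA` columns) and `triplets`, a tibble with
#'   `x_id`, `y_id`, `z_id`, `rho_xy`, `rho_xz`, `rho_zy`, `rho_xy_given_z`,
#'   `sensitivity`.
#' @export
triplet_scan <- function(pairs, mrna_es, lnc_es, mirna_es, s_threshold = 0.3) {
  stopifnot(inherits(mirna_es, "expression_set"))
  if (!identical(colnames(mrna_es$values), colnames(mirna_es$values))) {
    abort("miRNA set must share sample ordering with the pair matrices.")
  }
  if (nrow(pairs) == 0) abort("No pairs to scan.", class = "spongenet_empty")
  X <- mrna_es$values[pairs$x_id, , drop = FALSE]
  Y <- lnc_es$values[pairs$y_id, , drop = FALSE]
  Z <- mirna_es$values
  r_xz <- suppressWarnings(cor(t(X), t(Z), use = "pairwise.complete.obs"))
  r_zy <- suppressWarnings(cor(t(Z), t(Y), use = "pairwise.complete.obs"))
  zero_var <- apply(Z, 1L, function(z) sd(z, na.rm = TRUE) == 0 || all(is.na(z)))
  rxy <- pairs$rho_xy
  rxz_m <- r_xz          # pairs x miRNAs
  rzy_m <- t(r_zy)       # pairs x miRNAs
  prod_m <- rxz_m * rzy_m
  denom <- sqrt(1 - rxz_m^2) * sqrt(1 - rzy_m^2)
  partial <- (rxy - prod_m) / denom
  s_mat <- rxy - partial
  s_mat[, zero_var] <- NA_real_
  rownames(s_mat) <- paste(pairs$x_id, pairs$y_id, sep = "|")
  colnames(s_mat) <- rownames(Z)
  hits <- which(!is.na(s_mat) & s_mat > s_threshold, arr.ind = TRUE)
  triplets <- tibble(
    x_id = pairs$x_id[hits[, 1]],
    y_id = pairs$y_id[hits[, 1]],
    z_id = rownames(Z)[hits[, 2]],
    rho_xy = rxy[hits[, 1]],
    rho_xz = rxz_m[hits],
    rho_zy = rzy_m[hits],
    rho_xy_given_z = partial[hits],
    sensitivity = s_mat[hits]
  ) %>% arrange(desc(.data$sensitivity))
  inform(sprintf(
    "sensitivity filter (S > %g): retained %d / %d (pair, miRNA) combinations",
    s_threshold, nrow(triplets), sum(!is.na(s_mat))
  ))
  list(s_matrix = s_mat, triplets = triplets)
}

#' Hypergeometric enrichment of shared seed sites
#'
#' Tests whether the combined 3'UTR + lncRNA transcript of a candidate pair is
#' enriched in match sites of the shared miRNA. The universe is the set of all
#' 6-mer windows across every indexed transcript (N), of which the miRNA's
#' total site occurrences are the successes (K); the pair's windows are the
#' sample (n) and its combined site count the observed successes (k). Returns
#' the one-sided upper tail `P(>= k)`.
#'
#' @param x_id,y_id transcript ids of the mRNA 3'UTR and lncRNA transcript.
#' @param z_id miRNA id.
#' @param index a `seed_index` from [build_seed_index()] covering all three.
#' @return Upper-tail hypergeometric p-value.
#' @export
enrichment_test <- function(x_id, y_id, z_id, index) {
  stopifnot(inherits(index, "seed_index"))
  w <- setNames(index$windows$windows, index$windows$transcript_id)
  if (!all(c(x_id, y_id) %in% names(w))) {
    abort(paste0("Transcript(s) missing from index: ",
                 paste(setdiff(c(x_id, y_id), names(w)), collapse = ", ")))
  }
  tot <- index$totals
  if (!z_id %in% tot$mirna_id) abort(paste0("miRNA missing from index: ", z_id))
  N <- sum(w)
  K <- tot$total_count[tot$mirna_id == z_id]
  n <- unname(w[x_id] + w[y_id])
  cnt <- index$counts
  k <- sum(cnt$count[cnt$mirna_id == z_id & cnt$transcript_id %in% c(x_id, y_id)])
  if (k > n || K > N) abort("Corrupt index: observed successes exceed windows.")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotate triplets with site counts and enrichment p-values
#'
#' @param triplets tibble from [triplet_scan()]`$triplets`.
#' @param index a `seed_index` covering all referenced transcripts and miRNAs.
#' @return The input with `site_count_x`, `site_count_y` and `enrichment_p`
#'   columns added.
#' @export
add_enrichment <- function(triplets, index) {
  stopifnot(inherits(index, "seed_index"))
  if (nrow(triplets) == 0) {
    return(triplets %>% mutate(site_count_x = double(0),
                               site_count_y = double(0),
                               enrichment_p = double(0)))
  }
  cnt_of <- function(tx, mir) {
    hit <- index$counts$transcript_id == tx & index$counts$mirna_id == mir
    s <- index$counts$count[hit]
    if (length(s)) s[1] else 0L
  }
  triplets %>%
    mutate(
      site_count_x = map2_dbl(.data$x_id, .data$z_id, cnt_of),
      site_count_y = map2_dbl(.data$y_id, .data$z_id, cnt_of),
      enrichment_p = pmap(list(.data$x_id, .data$y_id, .data$z_id),
                          function(x, y, z) enrichment_test(x, y, z, index)) %>%
        unlist()
    )
}

#' Export a sensitivity matrix or triplet table as TSV
#'
#' @param s_matrix pairs-by-miRNAs sensitivity matrix from [triplet_scan()].
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_sensitivity_matrix <- function(s_matrix, path) {
  out <- as_tibble(as.data.frame(s_matrix), rownames = "pair")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_sensitivity_matrix
#' @param triplets annotated triplet tibble from [add_enrichment()].
#' @export
write_triplets <- function(triplets, path) {
  readr::write_tsv(triplets, path, progress = FALSE)
  invisible(path)
}
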