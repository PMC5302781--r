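#' Paired isoform FPKM table
#'
#' Couples two isoforms-by-patients FPKM matrices (normal and cancer, same
#' patients in the same order) with an optional per-isoform annotation of
#' which miRNA-cluster match sites its exonic sequence carries.
#'
#' @param normal,cancer numeric matrices, rows = isoforms (shared rownames),
#'   columns = patients (shared colnames), FPKM >= 0.
#' @param sites optional tibble `isoform_id`, `clusters` (list-column of
#'   character vectors of miRNA-cluster names; empty = no site).
#' @return An object of class `isoform_table`.
#' @export
isoform_table <- function(normal, cancer, sites = NULL) {
  if (!identical(rownames(normal), rownames(cancer))) {
    abort("Normal and cancer matrices must share isoform rownames.")
  }
  if (!identical(colnames(normal), colnames(cancer))) {
    unpaired <- c(setdiff(colnames(normal), colnames(cancer)),
                  setdiff(colnames(cancer), colnames(normal)))
    abort(paste0("Unpaired patient(s): ", paste(unpaired, collapse = ", ")))
  }
  if (any(normal < 0, na.rm = TRUE) || any(cancer < 0, na.rm = TRUE)) {
    abort("FPKM values must be non-negative.")
  }
  if (is.null(sites)) {
    sites <- tibble(isoform_id = rownames(normal),
                    clusters = rep(list(character(0)), nrow(normal)))
  }
  structure(list(normal = normal, cancer = cancer, sites = as_tibble(sites)),
            class = "isoform_table")
}

#' @export
print.isoform_table <- function(x, ...) {
  cat("<isoform_table>", nrow(x$normal), "isoforms x", ncol(x$normal),
      "patients (paired normal/cancer);",
      sum(lengths(x$sites$clusters) > 0), "isoform(s) carry a match site\n")
  invisible(x)
}

#' Read an isoform table from per-condition TSV files
#'
#' Each file mirrors the one-sheet-per-condition layout: rows are isoforms
#' (first column `isoform_id`), columns are patients.
#'
#' @param normal_path,cancer_path TSV paths.
#' @param sites optional site-annotation tibble, see [isoform_table()].
#' @return An [isoform_table()].
#' @export
read_isoform_table <- function(normal_path, cancer_path, sites = NULL) {
  read_one <- function(p) {
    tbl <- readr::read_tsv(p, na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
    m <- as.matrix(tbl[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(tbl[[1]])
    m
  }
  isoform_table(read_one(normal_path), read_one(cancer_path), sites)
}

#' Annotate isoforms with miRNA-cluster site flags from sequence
#'
#' Scans each isoform's (spliced) sequence for each cluster's 6-mer match
#' site, as in [build_seed_index()], and records which clusters hit.
#'
#' @param tbl an [isoform_table()].
#' @param sequences tibble `id`, `sequence` covering the isoforms.
#' @param clusters tibble `cluster`, `match_site` (DNA 6-mer per cluster).
#' @return The table with its `sites` annotation replaced.
#' @export
annotate_isoform_sites <- function(tbl, sequences, clusters) {
  stopifnot(inherits(tbl, "isoform_table"))
  seq_of <- setNames(sequences$sequence, sequences$id)
  missing <- setdiff(rownames(tbl$normal), names(seq_of))
  if (length(missing)) {
    abort(paste0("No sequence for isoform(s): ", paste(missing, collapse = ", ")))
  }
  sites <- tibble(
    isoform_id = rownames(tbl$normal),
    clusters = map(rownames(tbl$normal), function(id) {
      hit <- map_int(clusters$match_site,
                     function(s) count_sites(seq_of[[id]], s)) > 0
      clusters$cluster[hit]
    })
  )
  tbl$sites <- sites
  tbl
}

#' Paired Student's t-test p-value
#'
#' Two-sided paired t-test on the per-patient differences. Degenerate cases
#' follow the natural limits of the statistic: all differences zero gives
#' p = 1 (no evidence of change), while identical non-zero differences (zero
#' variance, non-zero mean) give p = 0 (the t statistic diverges).
#'
#' @param normal,cancer equal-length paired profiles, n >= 2.
#' @param paired set `FALSE` for an unpaired Welch test (sensitivity checks
#'   only; the matched design warrants the paired default).
#' @return Two-sided p-value.
#' @export
paired_ttest <- function(normal, cancer, paired = TRUE) {
  if (length(normal) != length(cancer)) abort("Profiles must be paired.")
  if (length(normal) < 2) abort("Need at least 2 pairs.")
  if (paired) {
    d <- cancer - normal
    if (all(d == 0)) return(1)
    if (sd(d) == 0) return(0)
  } else if (sd(normal) == 0 && sd(cancer) == 0) {
    return(if (mean(normal) == mean(cancer)) 1 else 0)
  }
  t.test(cancer, normal, paired = paired)$p.value
}

#' Filter isoforms by paired t-test
#'
#' Retains the isoforms whose normal/cancer fold change is statistically
#' significant (`p < alpha`, strict). The per-isoform p-values are reported
#' via `message()` and attached as attribute `"pvalues"`.
#'
#' @param tbl an [isoform_table()].
#' @param alpha significance level (default 0.05).
#' @return The filtered [isoform_table()].
#' @export
filter_isoforms <- function(tbl, alpha = 0.05) {
  stopifnot(inherits(tbl, "isoform_table"))
  p <- vapply(seq_len(nrow(tbl$normal)), function(i) {
    paired_ttest(tbl$normal[i, ], tbl$cancer[i, ])
  }, numeric(1))
  names(p) <- rownames(tbl$normal)
  keep <- p < alpha
  inform(paste0(
    sprintf("t-test filter (p < %g): retained %d / %d isoforms\n",
            alpha, sum(keep), length(keep)),
    paste(sprintf("  %s p=%.3g%s", names(p), p,
                  ifelse(keep, "", " (dropped)")), collapse = "\n")
  ))
  if (!any(keep)) abort("No isoform passes the t-test filter.",
                        class = "spongenet_empty")
  out <- isoform_table(
    tbl$normal[keep, , drop = FALSE],
    tbl$cancer[keep, , drop = FALSE],
    tbl$sites %>% filter(.data$isoform_id %in% names(p)[keep])
  )
  attr(out, "pvalues") <- p
  out
}

#' Per-isoform shares of total gene abundance
#'
#' Each isoform's mean FPKM over the condition's samples, as a percentage of
#' the summed means over all isoforms. Shares sum to 100 by construction.
#'
#' @param tbl an [isoform_table()].
#' @param condition `"normal"` or `"cancer"`.
#' @return Tibble `isoform_id`, `mean_fpkm`, `share_pct`.
#' @export
abundance_shares <- function(tbl, condition = c("normal", "cancer")) {
  stopifnot(inherits(tbl, "isoform_table"))
  condition <- match.arg(condition)
  m <- tbl[[condition]]
  means <- rowMeans(m, na.rm = TRUE)
  total <- sum(means)
  if (total <= 0) abort("Total abundance is zero: shares undefined.")
  tibble(
    isoform_id = rownames(m),
    mean_fpkm = unname(means),
    share_pct = unname(100 * means / total)
  )
}

#' Per-patient isoform variation matrix
#'
#' Entry (i, p) is the cancer-minus-normal FPKM difference of isoform i in
#' patient p: the observations handed to [pca_variation()] are isoforms and
#' the variables are patients.
#'
#' @param tbl an [isoform_table()].
#' @return Numeric matrix, rows = isoforms, columns = patients.
#' @export
variation_matrix <- function(tbl) {
  stopifnot(inherits(tbl, "isoform_table"))
  tbl$cancer - tbl$normal
}

#' Covariance PCA of a variation matrix
#'
#' Classical covariance-based PCA: columns (variables) are mean-centered, no
#' scaling to unit variance. Eigenvalues come in descending order; `scores`
#' (observations x components) is the representation of the centered data in
#' the component space and `factors` (variables x components) the orthonormal
#' transformation matrix, so `centered data = scores %*% t(factors)`. Factor
#' signs are fixed so each column's largest-magnitude entry is positive.
#'
#' @param data observations-by-variables numeric matrix, n >= 2 observations.
#' @return An object of class `pca_result`: list with `eigenvalues`,
#'   `explained` (variance fractions), `scores`, `factors`, `center`.
#' @export
pca_variation <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) abort("Need at least 2 observations for PCA.")
  ctr <- colMeans(data)
  xc <- sweep(data, 2, ctr)
  sv <- svd(xc)
  d2 <- sv$d^2
  if (sum(d2) <= .Machine$double.eps) {
    abort("All eigenvalues are zero: explained fractions undefined.")
  }
  eig <- d2 / (nrow(data) - 1)
  # sign convention: largest-|loading| entry of each factor column positive
  flip <- vapply(seq_along(sv$d), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  factors <- sweep(sv$v, 2, flip, `*`)
  scores <- xc %*% factors
  rn <- rownames(data) %||% paste0("obs", seq_len(nrow(data)))
  cn <- colnames(data) %||% paste0("var", seq_len(ncol(data)))
  pcs <- paste0("PC", seq_along(eig))
  dimnames(scores) <- list(rn, pcs)
  dimnames(factors) <- list(cn, pcs)
  structure(
    list(eigenvalues = eig, explained = eig / sum(eig),
         scores = scores, factors = factors, center = ctr),
    class = "pca_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", length(x$eigenvalues), "components;",
      sprintf("top-2 explained variance %.1f%%\n",
              100 * sum(x$explained[seq_len(min(2, length(x$explained)))])))
  invisible(x)
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    explained_pct = 100 * x$explained,
    cumulative_pct = 100 * cumsum(x$explained)
  )
}

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble(
    n_components = length(x$eigenvalues),
    top1_explained_pct = 100 * x$explained[1],
    top2_explained_pct = 100 * sum(x$explained[seq_len(min(2, length(x$explained)))])
  )
}

#' Isoform-to-miRNA abundance ratio
#'
#' The titration diagnostic: the ratio of an isoform's mean FPKM to the
#' miRNA's mean FPKM within each condition, plus the per-patient ratio
#' distributions and a paired t-test comparing them between conditions. A
#' sponge isoform whose ratio collapses in cancer has lost the concentration
#' parity the sponge mechanism needs.
#'
#' @param tbl an [isoform_table()].
#' @param isoform_id isoform to evaluate.
#' @param mirna_normal,mirna_cancer paired per-patient miRNA FPKM profiles in
#'   the table's patient order.
#' @return List with `ratios` (tibble `condition`, `ratio` of means),
#'   `per_patient` (tibble `patient`, `condition`, `ratio`) and `p_value`
#'   (paired t-test between the per-patient ratio profiles).
#' @export
ratio_to_mirna <- function(tbl, isoform_id, mirna_normal, mirna_cancer) {
  stopifnot(inherits(tbl, "isoform_table"))
  if (!isoform_id %in% rownames(tbl$normal)) {
    abort(paste0("Unknown isoform: ", isoform_id))
  }
  if (length(mirna_normal) != ncol(tbl$normal) ||
      length(mirna_cancer) != ncol(tbl$cancer)) {
    abort("miRNA profiles must cover the table's patients.")
  }
  mn <- mean(mirna_normal); mc <- mean(mirna_cancer)
  if (mn <= 0 || mc <= 0) abort("Zero miRNA mean: ratio undefined.")
  iso_n <- tbl$normal[isoform_id, ]
  iso_c <- tbl$cancer[isoform_id, ]
  pts <- colnames(tbl$normal)
  rn <- iso_n / mirna_normal
  rc <- iso_c / mirna_cancer
  list(
    ratios = tibble(
      condition = c("normal", "cancer"),
      ratio = c(mean(iso_n) / mn, mean(iso_c) / mc)
    ),
    per_patient = tibble(
      patient = rep(pts, 2),
      condition = rep(c("normal", "cancer"), each = length(pts)),
      ratio = c(rn, rc)
    ),
    p_value = paired_ttest(rn, rc)
  )
}

#' Differential exon usage comparison
#'
#' Per exon: the cancer/normal ratio of mean normalised counts and a paired
#' t-test p-value; exons with fold > 1 and p < `alpha` are flagged as
#' up-regulated. Counts are accepted as normalised upstream.
#'
#' @param normal_counts,cancer_counts exons-by-samples matrices of normalised
#'   counts with shared dimnames (columns paired by position).
#' @param alpha flag level (default 0.05).
#' @return Tibble `exon`, `mean_normal`, `mean_cancer`, `fold`, `p_value`,
#'   `flagged`; a zero normal mean leaves `fold` `NA` and `flagged` `NA`.
#' @export
exon_usage_comparison <- function(normal_counts, cancer_counts, alpha = 0.05) {
  if (!identical(dim(normal_counts), dim(cancer_counts))) {
    abort("Count matrices must have identical dimensions.")
  }
  mn <- rowMeans(normal_counts)
  mc <- rowMeans(cancer_counts)
  p <- vapply(seq_len(nrow(normal_counts)), function(i) {
    paired_ttest(normal_counts[i, ], cancer_counts[i, ])
  }, numeric(1))
  fold <- ifelse(mn > 0, mc / mn, NA_real_)
  tibble(
    exon = rownames(normal_counts) %||% paste0("exon", seq_along(mn)),
    mean_normal = unname(mn),
    mean_cancer = unname(mc),
    fold = unname(fold),
    p_value = p,
    flagged = ifelse(is.na(fold), NA, fold > 1 & p < alpha)
  )
}

#' Full titration report
#'
#' Per isoform: condition means, abundance shares, fold change and t-test p;
#' per (isoform, reference miRNA): the abundance ratio in each condition.
#'
#' @param tbl an [isoform_table()].
#' @param mirna_normal,mirna_cancer paired reference-miRNA profiles.
#' @param mirna_id label for the reference miRNA.
#' @return An object of class `titration_report`: list with `isoforms` (tibble
#'   `isoform_id`, `mean_normal`, `mean_cancer`, `share_normal_pct`,
#'   `share_cancer_pct`, `fold_change`, `p_value`, `has_site`) and `ratios`
#'   (tibble `isoform_id`, `mirna_id`, `ratio_normal`, `ratio_cancer`,
#'   `ratio_p`).
#' @export
titration_report <- function(tbl, mirna_normal, mirna_cancer,
                             mirna_id = "miRNA") {
  stopifnot(inherits(tbl, "isoform_table"))
  sh_n <- abundance_shares(tbl, "normal")
  sh_c <- abundance_shares(tbl, "cancer")
  p <- vapply(seq_len(nrow(tbl$normal)), function(i) {
    paired_ttest(tbl$normal[i, ], tbl$cancer[i, ])
  }, numeric(1))
  fold <- ifelse(sh_n$mean_fpkm > 0, sh_c$mean_fpkm / sh_n$mean_fpkm, NA_real_)
  has_site <- lengths(tbl$sites$clusters[
    match(sh_n$isoform_id, tbl$sites$isoform_id)]) > 0
  isoforms <- tibble(
    isoform_id = sh_n$isoform_id,
    mean_normal = sh_n$mean_fpkm,
    mean_cancer = sh_c$mean_fpkm,
    share_normal_pct = sh_n$share_pct,
    share_cancer_pct = sh_c$share_pct,
    fold_change = fold,
    p_value = p,
    has_site = has_site
  )
  ratios <- map(sh_n$isoform_id, function(id) {
    r <- ratio_to_mirna(tbl, id, mirna_normal, mirna_cancer)
    tibble(
      isoform_id = id, mirna_id = mirna_id,
      ratio_normal = r$ratios$ratio[1],
      ratio_cancer = r$ratios$ratio[2],
      ratio_p = r$p_value
    )
  }) %>% bind_rows()
  structure(list(isoforms = isoforms, ratios = ratios),
            class = "titration_report")
}

#' @export
print.titration_report <- function(x, ...) {
  cat("<titration_report>", nrow(x$isoforms), "isoforms;",
      sum(x$isoforms$has_site), "with match site\n")
  invisible(x)
}

#' @method tidy titration_report
#' @export
tidy.titration_report <- function(x, ...) {
  x$isoforms %>% left_join(x$ratios, by = "isoform_id")
}

#' Write a titration report as TSV + JSON
#'
#' @param report a [titration_report()].
#' @param tsv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_titration_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "titration_report"))
  if (!is.null(tsv_path)) readr::write_tsv(tidy(report), tsv_path, progress = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(isoforms = report$isoforms, ratios = report$ratios),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(c(tsv_path, json_path))
}
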