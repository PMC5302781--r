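#' Expression set container
#'
#' An `expression_set` couples an entities-by-samples matrix of non-negative
#' FPKM values (missing cells as `NA`) with per-sample metadata: the sample id,
#' the patient it came from and its condition (`"normal"` or `"cancer"`).
#' Matched designs carry each patient at most once per condition.
#'
#' @param values numeric matrix, rows = entities (rownames required),
#'   columns = samples (colnames required). Values must be `>= 0` or `NA`.
#' @param samples data frame with columns `sample_id`, `patient_id`,
#'   `condition`; one row per column of `values`, in matching order.
#' @param role entity role, one of `"mRNA"`, `"lncRNA"`, `"miRNA"`, `"isoform"`.
#'
#' @return An object of class `expression_set`: a list with elements `values`,
#'   `samples` (tibble) and `role`.
#' @export
expression_set <- function(values, samples, role = c("mRNA", "lncRNA", "miRNA", "isoform")) {
  role <- match.arg(role)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have entity rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste0(
      "Duplicate entity ids: ",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")
    ))
  }
  if (any(values < 0, na.rm = TRUE)) abort("FPKM values must be non-negative.")
  samples <- as_tibble(samples)
  needed <- c("sample_id", "patient_id", "condition")
  if (!all(needed %in% names(samples))) {
    abort("`samples` needs columns sample_id, patient_id, condition.")
  }
  if (!identical(as.character(samples$sample_id), colnames(values))) {
    abort("`samples$sample_id` must match colnames(values) in order.")
  }
  bad_cond <- setdiff(unique(samples$condition), c("normal", "cancer"))
  if (length(bad_cond)) {
    abort(paste0("Unknown condition label(s): ", paste(bad_cond, collapse = ", ")))
  }
  dup <- samples %>% dplyr::count(.data$patient_id, .data$condition) %>% filter(n > 1)
  if (nrow(dup)) {
    abort(paste0(
      "Patient appears more than once per condition: ",
      paste(dup$patient_id, collapse = ", ")
    ))
  }
  structure(
    list(values = values, samples = samples, role = role),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  n_missing <- sum(is.na(x$values))
  cat(
    "<expression_set> role:", x$role, "|",
    nrow(x$values), "entities x", ncol(x$values), "samples",
    sprintf("(%d normal, %d cancer; %d missing cells)\n",
            sum(x$samples$condition == "normal"),
            sum(x$samples$condition == "cancer"),
            n_missing)
  )
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Tidy view of an expression set
#'
#' @param x an [expression_set()].
#' @param ... unused.
#' @return A long tibble with columns `entity_id`, `sample_id`, `patient_id`,
#'   `condition`, `fpkm`.
#' @method as_tibble expression_set
#' @export
as_tibble.expression_set <- function(x, ...) {
  tibble(
    entity_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    fpkm = as.vector(x$values)
  ) %>%
    left_join(x$samples, by = "sample_id") %>%
    select("entity_id", "sample_id", "patient_id", "condition", "fpkm")
}

#' Subset an expression set to one condition
#'
#' @param es an [expression_set()].
#' @param condition `"normal"` or `"cancer"`.
#' @return An `expression_set` restricted to that condition's samples.
#' @export
filter_condition <- function(es, condition) {
  stopifnot(inherits(es, "expression_set"))
  keep <- es$samples$condition == condition
  if (!any(keep)) abort(paste0("No samples with condition '", condition, "'."))
  expression_set(es$values[, keep, drop = FALSE], es$samples[keep, ], es$role)
}

#' Read an FPKM expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds entity ids and whose
#' header row holds sample ids. Empty cells and `NA` are kept as missing
#' markers, never imputed. Each sample id must appear in `condition_map`.
#'
#' @param path TSV file path.
#' @param condition_map data frame with columns `sample_id`, `patient_id`,
#'   `condition` covering every sample in the file.
#' @param role entity role, see [expression_set()].
#' @return An [expression_set()].
#' @export
read_expression <- function(path, condition_map, role = "mRNA") {
  tbl <- readr::read_tsv(path, na = c("", "NA"), progress = FALSE,
                         show_col_types = FALSE)
  ids <- as.character(tbl[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate entity ids in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  condition_map <- as_tibble(condition_map)
  missing_samples <- setdiff(colnames(mat), condition_map$sample_id)
  if (length(missing_samples)) {
    abort(paste0(
      "Samples absent from condition map: ",
      paste(missing_samples, collapse = ", ")
    ))
  }
  samples <- condition_map[match(colnames(mat), condition_map$sample_id), ]
  expression_set(mat, samples, role)
}

#' Write an expression set to TSV
#'
#' Inverse of [read_expression()]: first column `entity_id`, one column per
#' sample; missing values written as empty cells.
#'
#' @param es an [expression_set()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(es, path) {
  stopifnot(inherits(es, "expression_set"))
  out <- as.data.frame(es$values)
  out <- cbind(entity_id = rownames(es$values), out)
  readr::write_tsv(as_tibble(out), path, na = "", progress = FALSE)
  invisible(path)
}

#' Apply the preprocessing filters to an expression set
#'
#' Drops entities with strictly more than `missing_max` missing values (as a
#' fraction of all samples, both conditions jointly) and, for mRNAs when
#' `utr_lengths` is supplied, entities whose 3'UTR is shorter than `utr_min`
#' nucleotides (the boundary is inclusive: a 500-nt UTR is retained at the
#' default). Order of retained entities is preserved, and counts retained and
#' dropped at each filter are reported via `message()`.
#'
#' @param es an [expression_set()].
#' @param utr_lengths named numeric vector of 3'UTR lengths (nt), required for
#'   the UTR filter; entities absent from it are dropped with the short ones.
#' @param missing_max maximum tolerated missing fraction (default 0.10, strict
#'   `>` comparison for dropping).
#' @param utr_min minimum 3'UTR length in nt (default 500, `>=` retains).
#' @return The filtered [expression_set()].
#' @export
preprocess_expression <- function(es, utr_lengths = NULL,
                                  missing_max = 0.10, utr_min = 500) {
  stopifnot(inherits(es, "expression_set"))
  n0 <- nrow(es$values)
  frac_missing <- rowMeans(is.na(es$values))
  keep <- frac_missing <= missing_max
  inform(sprintf(
    "missing-value filter (> %.0f%%): retained %d / %d entities",
    100 * missing_max, sum(keep), n0
  ))
  vals <- es$values[keep, , drop = FALSE]
  if (es$role == "mRNA" && !is.null(utr_lengths)) {
    len <- utr_lengths[rownames(vals)]
    keep_utr <- !is.na(len) & len >= utr_min
    inform(sprintf(
      "3'UTR-length filter (>= %d nt): retained %d / %d entities",
      utr_min, sum(keep_utr), nrow(vals)
    ))
    vals <- vals[keep_utr, , drop = FALSE]
  }
  if (nrow(vals) == 0L) {
    abort("Preprocessing dropped every entity.", class = "spongenet_empty")
  }
  expression_set(vals, es$samples, es$role)
}
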