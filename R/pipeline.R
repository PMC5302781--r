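#' Pipeline configuration
#'
#' All thresholds default to the method's published operating point:
#' pair-correlation percentile 99, sensitivity S > 0.3, enrichment p < 0.01,
#' isoform t-test p < 0.05, 3'UTR >= 500 nt, missing fraction <= 10%.
#' Configurations can be written and read as YAML; explicit arguments
#' override file values.
#'
#' @param input_dir directory with the dataset (layout of
#'   [write_sponge_dataset()]).
#' @param output_dir directory for pipeline outputs.
#' @param percentile,s_threshold,enrichment_alpha,ttest_alpha,utr_min,missing_max
#'   thresholds; see the module functions.
#' @param condition which condition's samples drive the inference
#'   (`"normal"` or `"cancer"`).
#' @param seed random seed echoed into manifests and used by `run_simulate()`.
#' @param ... further fields merged verbatim (e.g. simulator overrides).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            percentile = 99, s_threshold = 0.3,
                            enrichment_alpha = 0.01, ttest_alpha = 0.05,
                            utr_min = 500, missing_max = 0.10,
                            condition = "normal", seed = 1L, ...) {
  cfg <- c(as.list(environment()), list(...))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(name, lo, hi) {
    v <- cfg[[name]]
    if (!is.numeric(v) || v < lo || v > hi) {
      abort(sprintf("Config field `%s` out of range [%g, %g]: %s",
                    name, lo, hi, format(v)))
    }
  }
  chk("percentile", 0, 100)
  chk("s_threshold", -2, 2)
  chk("enrichment_alpha", 0, 1)
  chk("ttest_alpha", 0, 1)
  chk("utr_min", 0, Inf)
  chk("missing_max", 0, 1)
  if (!cfg$condition %in% c("normal", "cancer")) {
    abort("Config field `condition` must be 'normal' or 'cancer'.")
  }
  invisible(cfg)
}

#' Read / write pipeline configuration as YAML
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  vals <- modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Simulate a dataset into the configured input directory
#'
#' @param config a [pipeline_config()]; simulator parameters may be supplied
#'   as extra config fields matching [sponge_sim_params()] arguments.
#' @param overwrite allow writing into a non-empty directory?
#' @return The dataset directory, invisibly.
#' @export
run_simulate <- function(config, overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  extra <- config[intersect(names(config), names(formals(sponge_sim_params)))]
  extra$seed <- config$seed
  params <- do.call(sponge_sim_params, extra)
  ds <- simulate_sponge_dataset(params)
  write_sponge_dataset(ds, config$input_dir, overwrite = overwrite)
  invisible(config$input_dir)
}

#' Run the sponge-network inference pipeline
#'
#' preprocess -> top-pair selection -> triplet scan -> seed-match enrichment
#' -> network build -> export. Each stage logs before/after counts; a stage
#' with an empty result halts the pipeline with the stage's name.
#'
#' @param config a [pipeline_config()] whose `input_dir` holds the dataset.
#' @return Invisibly, a list with `network` ([mmi_network()]), `triplets`,
#'   `s_matrix`, `pairs`, and `index`. Outputs (edge list, GraphML, triplet
#'   TSV, sensitivity TSV, summary JSON, effective config YAML) land in
#'   `output_dir`.
#' @export
run_infer <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$input_dir
  cond_map <- readr::read_tsv(file.path(dir, "conditions.tsv"),
                              col_types = "ccc", progress = FALSE)
  mrna <- read_expression(file.path(dir, "mrna_fpkm.tsv"), cond_map, "mRNA")
  lnc <- read_expression(file.path(dir, "lncrna_fpkm.tsv"), cond_map, "lncRNA")
  mir <- read_expression(file.path(dir, "mirna_fpkm.tsv"), cond_map, "miRNA")
  utr <- read_transcript_fasta(file.path(dir, "utr.fasta"), "mRNA-3'UTR")
  lnc_seq <- read_transcript_fasta(file.path(dir, "lncrna.fasta"), "lncRNA-cDNA")
  mirnas <- mirna_seeds(read_mirna(file.path(dir, "mirna_mature.tsv")))

  utr_len <- setNames(utr$length, utr$id)
  mrna <- preprocess_expression(mrna, utr_len,
                                missing_max = config$missing_max,
                                utr_min = config$utr_min)
  lnc <- preprocess_expression(lnc, missing_max = config$missing_max)
  mir <- preprocess_expression(mir, missing_max = config$missing_max)

  mrna_c <- filter_condition(mrna, config$condition)
  lnc_c <- filter_condition(lnc, config$condition)
  mir_c <- filter_condition(mir, config$condition)

  pairs <- select_top_pairs(mrna_c, lnc_c, percentile = config$percentile)
  if (nrow(pairs) == 0) {
    abort("Pipeline halted at stage 'top-pair selection': no pairs retained.",
          class = "spongenet_empty")
  }
  scan <- triplet_scan(pairs, mrna_c, lnc_c, mir_c,
                       s_threshold = config$s_threshold)
  if (nrow(scan$triplets) == 0) {
    abort("Pipeline halted at stage 'triplet scan': no triplet passed S.",
          class = "spongenet_empty")
  }
  index <- build_seed_index(bind_rows(utr, lnc_seq), mirnas)
  triplets <- add_enrichment(scan$triplets, index)
  net <- build_network(
    triplets, enrichment_alpha = config$enrichment_alpha,
    provenance = list(
      percentile = config$percentile,
      rho_threshold = attr(pairs, "threshold"),
      s_threshold = config$s_threshold,
      condition = config$condition
    )
  )
  if (nrow(net$edges) == 0) {
    abort("Pipeline halted at stage 'network build': no edge passed enrichment.",
          class = "spongenet_empty")
  }
  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    export_network(net, file.path(out, "network_edges.tsv"), "tsv")
    export_network(net, file.path(out, "network.graphml"), "graphml")
    write_triplets(triplets, file.path(out, "triplets.tsv"))
    write_sensitivity_matrix(scan$s_matrix, file.path(out, "sensitivity.tsv"))
    write_network_summary(net, file.path(out, "summary.json"))
    write_pipeline_config(config, file.path(out, "config_used.yaml"))
  }
  invisible(list(network = net, triplets = triplets,
                 s_matrix = scan$s_matrix, pairs = pairs, index = index))
}

#' Run the isoform titration analysis
#'
#' t-test filter -> abundance shares -> variation matrix -> covariance PCA
#' -> isoform/miRNA ratios -> report.
#'
#' @param config a [pipeline_config()]; `input_dir` must hold
#'   `isoform_normal.tsv`, `isoform_cancer.tsv` and `mirna_reference.tsv`
#'   (two rows: normal and cancer per-patient profiles).
#' @param tbl,mirna_normal,mirna_cancer in-memory alternative to the files.
#' @return Invisibly, a list with `filtered` ([isoform_table()]), `report`
#'   ([titration_report()]), `pca` ([pca_variation()] result on the filtered
#'   variation matrix).
#' @export
run_isoform <- function(config, tbl = NULL, mirna_normal = NULL,
                        mirna_cancer = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(tbl)) {
    dir <- config$input_dir
    tbl <- read_isoform_table(file.path(dir, "isoform_normal.tsv"),
                              file.path(dir, "isoform_cancer.tsv"))
    mir <- readr::read_tsv(file.path(dir, "mirna_reference.tsv"),
                           progress = FALSE, show_col_types = FALSE)
    mirna_normal <- as.numeric(mir[mir[[1]] == "normal", -1])
    mirna_cancer <- as.numeric(mir[mir[[1]] == "cancer", -1])
  }
  filtered <- filter_isoforms(tbl, alpha = config$ttest_alpha)
  report <- titration_report(filtered, mirna_normal, mirna_cancer)
  pca <- pca_variation(variation_matrix(filtered))
  out <- config$output_dir
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    write_titration_report(report,
                           tsv_path = file.path(out, "titration_report.tsv"),
                           json_path = file.path(out, "titration_report.json"))
    readr::write_tsv(as_tibble(as.data.frame(pca$scores), rownames = "isoform_id"),
                     file.path(out, "pca_scores.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(as.data.frame(pca$factors), rownames = "patient"),
                     file.path(out, "pca_factors.tsv"), progress = FALSE)
    readr::write_tsv(tidy(pca), file.path(out, "pca_explained.tsv"),
                     progress = FALSE)
  }
  invisible(list(filtered = filtered, report = report, pca = pca))
}

#' Compare two exported networks
#'
#' @param path_a,path_b edge-list TSVs written by [export_network()].
#' @param output_path optional JSON path for the rewiring summary.
#' @return The [compare_networks()] result, invisibly.
#' @export
run_compare <- function(path_a, path_b, output_path = NULL) {
  cmp <- compare_networks(read_network_tsv(path_a), read_network_tsv(path_b))
  if (!is.null(output_path)) {
    jsonlite::write_json(
      list(summary = cmp$summary, degree_delta = head(cmp$degree_delta, 50)),
      output_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(cmp)
}
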