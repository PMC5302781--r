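#' Parameters for the synthetic sponge/titration generators
#'
#' The generators produce paired normal/cancer FPKM data with the statistical
#' structure the inference assumes: log-normal expression, miRNA-mediated
#' co-expression of planted sponge triplets through a shared multiplicative
#' repression term, confounded pairs co-expressed through a latent factor with
#' no miRNA involvement, independent background entities, and random
#' transcript sequences with seed-match sites planted into the sponge pairs.
#'
#' The log-scale dispersions default to a quasi-linear regime
#' (`repression_strength` 0.15, `noise_sd` 0.03, `mirna_sd` 0.05): since the
#' inference correlates raw FPKM values, mediated correlation only survives
#' the exponential link while dispersions are small, and these values place
#' the planted population sensitivity correlation near 0.63 (closed form via
#' [expected_triplet_correlations()]). Condition effects default to the
#' magnitudes characteristic of the breast-carcinoma setting: miRNAs up 4- to
#' 8-fold in cancer and the sponge gene's total abundance up about 2-fold.
#'
#' @param n_patients matched patients (default 72).
#' @param n_sponge_triplets planted (mRNA, lncRNA, miRNA) triplets (default 50).
#' @param n_confounded_pairs co-expressed pairs without miRNA mediation
#'   (default 50).
#' @param n_background background mRNAs/lncRNAs (each) and miRNAs
#'   (`ceiling(n_background / 2)`), all independent (default 50).
#' @param repression_strength gamma >= 0, log-scale repression of both sponge
#'   partners by their miRNA.
#' @param noise_sd sigma, log-scale sd of entity-level noise.
#' @param mirna_sd log-scale sd of miRNA profiles.
#' @param confounder_sd log-scale loading of the shared latent factor for
#'   confounded pairs.
#' @param mirna_fold_range cancer/normal fold-change range for planted miRNAs
#'   (default `c(4, 8)`; drawn uniformly per miRNA).
#' @param gene_fold cancer/normal fold change of total sponge-gene abundance
#'   in the titration generator (default 2).
#' @param utr_length_range,lnc_length_range sequence length ranges in nt.
#' @param planted_site_counts seed-match sites planted into each member of a
#'   sponge pair (default 5).
#' @param cancer_mediation keep miRNA mediation in the cancer condition?
#'   Default `FALSE`: the sponge program is switched off in cancer, so the two
#'   conditions rewire.
#' @param super_sponge if `TRUE`, all planted triplets share one lncRNA and
#'   one miRNA: the first lncRNA sponges the first miRNA against
#'   `n_sponge_triplets` mRNAs, planting a hub (default `FALSE`).
#' @param n_isoforms isoforms in the titration generator (default 10).
#' @param site_isoform_fold cancer/normal fold of the site-bearing isoform
#'   (default 1.3, a modest change against the miRNA's 4-8-fold).
#' @param n_exons,exon_breakpoint,exon_fold,exon_depth exon-count generator:
#'   number of exons, last non-affected exon, cancer fold past the
#'   breakpoint, mean normalised count.
#' @param seed integer random seed; the generators are pure functions of the
#'   full parameter set including the seed.
#' @return A validated list of class `sponge_sim_params`.
#' @export
sponge_sim_params <- function(n_patients = 72,
                              n_sponge_triplets = 50,
                              n_confounded_pairs = 50,
                              n_background = 50,
                              repression_strength = 0.15,
                              noise_sd = 0.03,
                              mirna_sd = 0.05,
                              confounder_sd = 0.15,
                              mirna_fold_range = c(4, 8),
                              gene_fold = 2,
                              utr_length_range = c(500, 1500),
                              lnc_length_range = c(1000, 3000),
                              planted_site_counts = 5,
                              cancer_mediation = FALSE,
                              super_sponge = FALSE,
                              n_isoforms = 10,
                              site_isoform_fold = 1.3,
                              n_exons = 9,
                              exon_breakpoint = 5,
                              exon_fold = 2,
                              exon_depth = 200,
                              seed = 1L) {
  p <- as.list(environment())
  counts <- c("n_patients", "n_sponge_triplets", "n_confounded_pairs",
              "n_background", "planted_site_counts", "n_isoforms",
              "n_exons", "exon_breakpoint")
  for (nm in counts) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0) {
      abort(paste0("`", nm, "` must be a non-negative count."))
    }
  }
  if (p$repression_strength < 0) abort("`repression_strength` must be >= 0.")
  if (any(p$mirna_fold_range < 1) || diff(p$mirna_fold_range) < 0) {
    abort("`mirna_fold_range` must be an increasing range >= 1.")
  }
  if (p$gene_fold < 1) abort("`gene_fold` must be >= 1.")
  if (p$exon_breakpoint >= p$n_exons && p$exon_breakpoint != p$n_exons) {
    abort("`exon_breakpoint` must be <= n_exons.")
  }
  if (p$n_patients < 2) abort("Need at least 2 patients.")
  structure(p, class = "sponge_sim_params")
}

#' Closed-form population correlations for a planted triplet
#'
#' Under the generator's log-normal model (`log Z` with sd `mirna_sd`,
#' `log X = const - gamma * Ztilde + noise`, `Ztilde` the standardised log
#' miRNA), every pairwise raw-scale Pearson correlation has the closed form
#' `(exp(cov) - 1) / sqrt((exp(v1) - 1) (exp(v2) - 1))` on the log-scale
#' covariances. This is the generator's analytic ground truth.
#'
#' @param gamma repression strength.
#' @param sigma entity noise sd (log scale).
#' @param mirna_sd miRNA sd (log scale).
#' @return Tibble with `rho_xy`, `rho_xz`, `rho_zy`, `rho_xy_given_z`,
#'   `sensitivity` (population values on the FPKM scale).
#' @export
expected_triplet_correlations <- function(gamma, sigma, mirna_sd) {
  ln_cor <- function(cab, va, vb) (exp(cab) - 1) / sqrt((exp(va) - 1) * (exp(vb) - 1))
  vx <- gamma^2 + sigma^2
  rho_xy <- ln_cor(gamma^2, vx, vx)
  rho_xz <- ln_cor(-gamma * mirna_sd, vx, mirna_sd^2)
  part <- partial_cor(rho_xy, rho_xz, rho_xz)
  tibble(
    rho_xy = rho_xy, rho_xz = rho_xz, rho_zy = rho_xz,
    rho_xy_given_z = part,
    sensitivity = rho_xy - part
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant_sites <- function(sequence, site, count) {
  k <- nchar(site)
  L <- nchar(sequence)
  if (count * k > L) {
    abort(sprintf("Cannot plant %d sites of %d nt into a %d-nt sequence.",
                  count, k, L))
  }
  if (count == 0) return(sequence)
  # non-overlapping slots on a k-spaced grid, then overwrite
  slots <- sample(seq_len(L %/% k), count)
  for (s in slots) {
    substr(sequence, (s - 1) * k + 1, s * k) <- site
  }
  sequence
}

#' Simulate a paired sponge expression dataset
#'
#' Generates mRNA, lncRNA and miRNA [expression_set()]s over matched
#' normal/cancer patients, transcript sequences with planted seed-match
#' sites, and the ground-truth lists of planted triplets and confounded
#' pairs. See [sponge_sim_params()] for the generative model.
#'
#' @param params a [sponge_sim_params()].
#' @return List with `mrna`, `lncrna`, `mirna` ([expression_set()]s),
#'   `utr_sequences`, `lnc_sequences` (tibbles as from
#'   [read_transcript_fasta()]), `mirnas` (tibble with seeds and sites),
#'   `truth` (list `triplets`, `confounded` tibbles) and `params`.
#' @export
simulate_sponge_dataset <- function(params = sponge_sim_params()) {
  stopifnot(inherits(params, "sponge_sim_params"))
  set.seed(params$seed)
  n <- params$n_patients
  nt <- params$n_sponge_triplets
  nc <- params$n_confounded_pairs
  nb <- params$n_background
  nbz <- ceiling(nb / 2)
  gamma <- params$repression_strength
  sigma <- params$noise_sd
  sz <- params$mirna_sd

  patients <- sprintf("P%03d", seq_len(n))
  samples <- tibble(
    sample_id = c(paste0(patients, "_N"), paste0(patients, "_C")),
    patient_id = rep(patients, 2),
    condition = rep(c("normal", "cancer"), each = n)
  )

  mrna_ids <- sprintf("mRNA_%03d", seq_len(nt + nc + nb))
  lnc_ids <- sprintf("lncRNA_%03d", seq_len(nt + nc + nb))
  mir_ids <- sprintf("miR_%03d", seq_len(nt + nbz))

  base_mrna <- rlnorm(nt + nc + nb, log(50), 0.3)
  base_lnc <- rlnorm(nt + nc + nb, log(20), 0.3)
  base_mir <- rlnorm(nt + nbz, log(30), 0.3)
  mir_fold <- runif(nt + nbz, params$mirna_fold_range[1], params$mirna_fold_range[2])

  gen_cond <- function(mediated) {
    zt <- matrix(rnorm((nt + nbz) * n), nt + nbz, n)     # standardised log-miRNA
    Z <- exp(log(base_mir) + sz * zt)
    X <- matrix(NA_real_, nt + nc + nb, n)
    Y <- matrix(NA_real_, nt + nc + nb, n)
    g_eff <- if (mediated) gamma else 0
    if (params$super_sponge) {
      for (i in seq_len(nt)) {
        X[i, ] <- base_mrna[i] * exp(-g_eff * zt[1, ] + sigma * rnorm(n))
      }
      Y[1, ] <- base_lnc[1] * exp(-g_eff * zt[1, ] + sigma * rnorm(n))
      for (i in seq(2, length.out = max(nt - 1, 0))) {
        Y[i, ] <- base_lnc[i] * exp((gamma + sigma) * rnorm(n))
      }
    } else {
      for (i in seq_len(nt)) {
        X[i, ] <- base_mrna[i] * exp(-g_eff * zt[i, ] + sigma * rnorm(n))
        Y[i, ] <- base_lnc[i] * exp(-g_eff * zt[i, ] + sigma * rnorm(n))
      }
    }
    for (j in seq_len(nc)) {
      L <- rnorm(n)  # shared latent factor, no miRNA involvement
      X[nt + j, ] <- base_mrna[nt + j] *
        exp(params$confounder_sd * L + sigma * rnorm(n))
      Y[nt + j, ] <- base_lnc[nt + j] *
        exp(params$confounder_sd * L + sigma * rnorm(n))
    }
    bg <- seq(nt + nc + 1, length.out = nb)
    for (b in bg) {
      X[b, ] <- base_mrna[b] * exp((gamma + sigma) * rnorm(n))
      Y[b, ] <- base_lnc[b] * exp((gamma + sigma) * rnorm(n))
    }
    list(X = X, Y = Y, Z = Z)
  }

  normal <- gen_cond(mediated = TRUE)
  cancer <- gen_cond(mediated = params$cancer_mediation)
  cancer$Z <- cancer$Z * mir_fold            # 4-8-fold miRNA up-regulation
  cancer$Y[seq_len(nt), ] <- cancer$Y[seq_len(nt), ] * params$gene_fold

  as_es <- function(Nm, Cm, ids, role) {
    m <- cbind(Nm, Cm)
    rownames(m) <- ids
    colnames(m) <- samples$sample_id
    expression_set(m, samples, role)
  }
  mrna_es <- as_es(normal$X, cancer$X, mrna_ids, "mRNA")
  lnc_es <- as_es(normal$Y, cancer$Y, lnc_ids, "lncRNA")
  mir_es <- as_es(normal$Z, cancer$Z, mir_ids, "miRNA")

  # mature miRNAs: random 22-mers; seed = positions 2-7
  matures <- vapply(seq_len(nt + nbz), function(i) {
    chartr("T", "U", random_dna(22))
  }, character(1))
  mirnas <- mirna_seeds(tibble(mirna_id = mir_ids, mature_sequence = matures))

  utr_len <- sample(params$utr_length_range[1]:params$utr_length_range[2],
                    nt + nc + nb, replace = TRUE)
  lnc_len <- sample(params$lnc_length_range[1]:params$lnc_length_range[2],
                    nt + nc + nb, replace = TRUE)
  utr_seq <- vapply(utr_len, random_dna, character(1))
  lnc_seq <- vapply(lnc_len, random_dna, character(1))
  if (params$super_sponge) {
    for (i in seq_len(nt)) {
      utr_seq[i] <- plant_sites(utr_seq[i], mirnas$match_site[1],
                                params$planted_site_counts)
    }
    lnc_seq[1] <- plant_sites(lnc_seq[1], mirnas$match_site[1],
                              params$planted_site_counts)
  } else {
    for (i in seq_len(nt)) {
      utr_seq[i] <- plant_sites(utr_seq[i], mirnas$match_site[i],
                                params$planted_site_counts)
      lnc_seq[i] <- plant_sites(lnc_seq[i], mirnas$match_site[i],
                                params$planted_site_counts)
    }
  }
  utr_sequences <- tibble(id = mrna_ids, role = "mRNA-3'UTR",
                          sequence = utr_seq, length = nchar(utr_seq))
  lnc_sequences <- tibble(id = lnc_ids, role = "lncRNA-cDNA",
                          sequence = lnc_seq, length = nchar(lnc_seq))

  truth <- list(
    triplets = tibble(
      x_id = mrna_ids[seq_len(nt)],
      y_id = if (params$super_sponge) rep(lnc_ids[1], nt) else lnc_ids[seq_len(nt)],
      z_id = if (params$super_sponge) rep(mir_ids[1], nt) else mir_ids[seq_len(nt)]
    ),
    confounded = tibble(
      x_id = mrna_ids[seq(nt + 1, length.out = nc)],
      y_id = lnc_ids[seq(nt + 1, length.out = nc)]
    )
  )
  list(
    mrna = mrna_es, lncrna = lnc_es, mirna = mir_es,
    utr_sequences = utr_sequences, lnc_sequences = lnc_sequences,
    mirnas = mirnas, truth = truth, params = params
  )
}

#' Simulate the isoform titration dataset
#'
#' Ten isoforms by default: a dominant site-free isoform (about half the
#' gene's abundance in normal tissue) absorbs the roughly 2-fold cancer
#' up-regulation of the total; a site-bearing isoform (about 15% share)
#' changes modestly (`site_isoform_fold`); the remaining isoforms are
#' low-abundance and null. The paired reference miRNA rises by a factor drawn
#' from `mirna_fold_range`, so on the raw-concentration scale the site
#' isoform's isoform/miRNA ratio collapses in cancer while its own abundance
#' barely moves — the titration signature.
#'
#' @param params a [sponge_sim_params()].
#' @return List with `table` (an [isoform_table()] with site annotation),
#'   `mirna_normal`, `mirna_cancer` (per-patient profiles), `mirna_fold`, and
#'   `truth` (tibble `isoform_id`, `has_site`, `class`).
#' @export
simulate_isoform_titration <- function(params = sponge_sim_params()) {
  stopifnot(inherits(params, "sponge_sim_params"))
  set.seed(params$seed + 1L)
  n <- params$n_patients
  k <- max(5L, as.integer(params$n_isoforms))
  patients <- sprintf("P%03d", seq_len(n))
  iso_ids <- sprintf("Iso%02d", seq_len(k))

  total_normal <- 100
  mean_n <- c(0.50 * total_normal, 0.15 * total_normal,
              rep(0.35 * total_normal / (k - 2), k - 2))
  mean_c <- mean_n
  mean_c[2] <- mean_n[2] * params$site_isoform_fold
  # dominant isoform absorbs the total-abundance fold change
  mean_c[1] <- params$gene_fold * total_normal - sum(mean_c[-1])
  sigma <- 0.2  # per-measurement log-normal dispersion of the isoform FPKMs

  draw <- function(means) {
    m <- vapply(means, function(mu) mu * exp(sigma * rnorm(n) - sigma^2 / 2),
                numeric(n))
    m <- t(m)
    dimnames(m) <- list(iso_ids, patients)
    m
  }
  normal <- draw(mean_n)
  cancer <- draw(mean_c)
  sites <- tibble(
    isoform_id = iso_ids,
    clusters = c(list(character(0)), list("miR-200b/200c/429"),
                 rep(list(character(0)), k - 2))
  )
  tbl <- isoform_table(normal, cancer, sites)

  mir_fold <- runif(1, params$mirna_fold_range[1], params$mirna_fold_range[2])
  mir_mean_n <- 15  # comparable to the site isoform in normal tissue
  mirna_normal <- mir_mean_n * exp(sigma * rnorm(n) - sigma^2 / 2)
  mirna_cancer <- mir_mean_n * mir_fold * exp(sigma * rnorm(n) - sigma^2 / 2)

  truth <- tibble(
    isoform_id = iso_ids,
    has_site = seq_len(k) == 2,
    class = c("dominant-no-site", "site-bearing", rep("background", k - 2))
  )
  list(table = tbl, mirna_normal = mirna_normal, mirna_cancer = mirna_cancer,
       mirna_fold = mir_fold, truth = truth)
}

#' Simulate normalised exon counts with a downstream up-regulation
#'
#' Negative-binomial counts for `n_exons` exons over matched samples; in
#' cancer, exons strictly past `exon_breakpoint` have their mean multiplied
#' by `exon_fold`.
#'
#' @param params a [sponge_sim_params()].
#' @return List with `normal`, `cancer` (exons-by-samples matrices) and
#'   `truth` (tibble `exon`, `upregulated`).
#' @export
simulate_exon_counts <- function(params = sponge_sim_params()) {
  stopifnot(inherits(params, "sponge_sim_params"))
  set.seed(params$seed + 2L)
  n <- params$n_patients
  k <- params$n_exons
  bp <- params$exon_breakpoint
  exon_ids <- sprintf("exon%02d", seq_len(k))
  patients <- sprintf("P%03d", seq_len(n))
  mu <- rep(params$exon_depth, k)
  up <- seq_len(k) > bp
  draw <- function(means) {
    m <- t(vapply(means, function(m0) rnbinom(n, mu = m0, size = 20), numeric(n)))
    dimnames(m) <- list(exon_ids, patients)
    m
  }
  normal <- draw(mu)
  cancer <- draw(ifelse(up, mu * params$exon_fold, mu))
  list(normal = normal, cancer = cancer,
       truth = tibble(exon = exon_ids, upregulated = up & params$exon_fold > 1))
}

#' Write a simulated sponge dataset in the pipeline's input formats
#'
#' Writes the three expression TSVs, the condition table, the two FASTA
#' files, the miRNA table and a ground-truth JSON into `dir`, exactly the
#' formats the readers in this package consume.
#'
#' @param dataset output of [simulate_sponge_dataset()].
#' @param dir output directory (created if absent).
#' @param overwrite allow writing into a non-empty directory?
#' @return `dir` invisibly.
#' @export
write_sponge_dataset <- function(dataset, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    abort(paste0("Output directory not empty: ", dir,
                 " (use overwrite = TRUE)."))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(dataset$mrna, file.path(dir, "mrna_fpkm.tsv"))
  write_expression(dataset$lncrna, file.path(dir, "lncrna_fpkm.tsv"))
  write_expression(dataset$mirna, file.path(dir, "mirna_fpkm.tsv"))
  readr::write_tsv(dataset$mrna$samples, file.path(dir, "conditions.tsv"),
                   progress = FALSE)
  write_fasta <- function(tbl, path) {
    writeLines(paste0(">", tbl$id, "\n", tbl$sequence), path)
  }
  write_fasta(dataset$utr_sequences, file.path(dir, "utr.fasta"))
  write_fasta(dataset$lnc_sequences, file.path(dir, "lncrna.fasta"))
  readr::write_tsv(dataset$mirnas %>% select("mirna_id", "mature_sequence"),
                   file.path(dir, "mirna_mature.tsv"), col_names = FALSE,
                   progress = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- c(list(seed = dataset$params$seed),
                unclass(dataset$params)[c(
                  "n_patients", "n_sponge_triplets", "n_confounded_pairs",
                  "n_background", "repression_strength", "noise_sd",
                  "mirna_sd", "mirna_fold_range", "gene_fold",
                  "planted_site_counts")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
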