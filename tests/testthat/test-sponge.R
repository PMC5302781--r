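test_that("Pearson correlation handles identity, sign and hand-computed case", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cor(x, x), 1)
  expect_equal(pearson_cor(x, -x), -1)
  expect_lt(abs(pearson_cor(c(1, 2, 3), c(1, 2, 4)) - 0.982), 1e-3)
  expect_warning(out <- pearson_cor(c(1, 1, 1), c(1, 2, 3)), "Zero variance")
  expect_true(is.na(out))
  expect_error(pearson_cor(c(1, NA, 3, NA), c(NA, 2, 3, 4)), "Fewer than 3")
})

test_that("partial correlation matches the closed form and its edge cases", {
  # no mediation: conditioning on an uncorrelated Z changes nothing
  expect_equal(partial_cor(0.55, 0, 0), 0.55)
  expect_lt(abs(partial_cor(0.8, 0.5, 0.5) - 0.7333), 1e-4)
  expect_lt(abs(partial_cor(0.8, -0.8, -0.8) - 0.4444), 1e-4)
  expect_warning(out <- partial_cor(0.5, 1, 0.2), "undefined")
  expect_true(is.na(out))
})

test_that("sensitivity is the exact Pearson-minus-partial difference", {
  expect_equal(sensitivity_cor(0.62, 0.62), 0)
  expect_lt(abs(sensitivity_cor(0.8, partial_cor(0.8, 0.5, 0.5)) - 0.0667),
            1e-4)
  s <- sensitivity_cor(0.8, partial_cor(0.8, -0.8, -0.8))
  expect_lt(abs(s - 0.3556), 1e-4)
  expect_gt(s, 0.3)  # clears the triplet selection threshold
})

test_that("partial correlation reproduces the regression-residual definition", {
  set.seed(11)
  n <- 1e5
  z <- rnorm(n)
  x <- 0.7 * z + rnorm(n)
  y <- -0.5 * z + rnorm(n)
  r_formula <- partial_cor(cor(x, y), cor(x, z), cor(z, y))
  r_resid <- cor(residuals(lm(x ~ z)), residuals(lm(y ~ z)))
  expect_equal(r_formula, r_resid, tolerance = 0.01)
})

test_that("uncorrelated miRNA with correlated pair gives negative sensitivity", {
  # closed form: rho_xz = 0 makes partial = rho_xy / sqrt(1 - rho_zy^2) > rho_xy
  for (rho_xy in c(0.2, 0.5, 0.9)) {
    for (rho_zy in c(-0.6, 0.3, 0.8)) {
      s <- sensitivity_cor(rho_xy, partial_cor(rho_xy, 0, rho_zy))
      expect_lt(s, 0)
    }
  }
})

test_that("top-pair selection applies a strict empirical-percentile cut", {
  set.seed(5)
  # 10 x 10 grid -> 100 pairs with distinct correlations
  base <- matrix(rnorm(10 * 30), 10, 30)
  mrna <- make_es(exp(base + matrix(rnorm(300, sd = 0.5), 10, 30)), "mRNA")
  lnc <- make_es(exp(base[sample(10), ] + matrix(rnorm(300, sd = 0.5), 10, 30)),
                 "lncRNA")
  pairs <- suppressMessages(select_top_pairs(mrna, lnc, percentile = 99))
  expect_equal(nrow(pairs), 1L)  # exactly the top pair out of 100
  cc <- cor(t(mrna$values), t(lnc$values))
  expect_equal(pairs$rho_xy, max(cc))
  expect_identical(pairs$x_id, rownames(cc)[which(cc == max(cc), arr.ind = TRUE)[1]])
})

test_that("all-equal correlations select nothing (strict > threshold)", {
  m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 2, 4, byrow = TRUE)
  mrna <- make_es(m, "mRNA")
  lnc <- make_es(m * 3, "lncRNA")
  pairs <- suppressMessages(suppressWarnings(select_top_pairs(mrna, lnc)))
  expect_equal(nrow(pairs), 0L)
})

test_that("triplet scan matches per-triplet recomputation and flags mediators", {
  set.seed(21)
  n <- 72
  zt <- rnorm(n)
  mk <- function(g) exp(4 - g * zt + 0.03 * rnorm(n))
  mrna <- make_es(rbind(mk(0.15), exp(4 + 0.1 * rnorm(n))), "mRNA")
  lnc <- make_es(rbind(mk(0.15), exp(3 + 0.1 * rnorm(n))), "lncRNA")
  mir <- make_es(rbind(exp(3 + 0.05 * zt), exp(3 + 0.05 * rnorm(n)),
                       matrix(5, 1, n)), "miRNA")
  pairs <- suppressMessages(select_top_pairs(mrna, lnc, percentile = 50))
  scan <- suppressMessages(triplet_scan(pairs, mrna, lnc, mir, s_threshold = 0.3))
  # compositional identity: every matrix cell equals the scalar recomputation
  for (i in seq_len(nrow(pairs))) {
    for (m in rownames(mir$values)[1:2]) {
      x <- mrna$values[pairs$x_id[i], ]
      y <- lnc$values[pairs$y_id[i], ]
      z <- mir$values[m, ]
      expected <- sensitivity_cor(
        pairs$rho_xy[i],
        partial_cor(pairs$rho_xy[i], pearson_cor(x, z), pearson_cor(z, y))
      )
      expect_equal(scan$s_matrix[paste(pairs$x_id[i], pairs$y_id[i], sep = "|"), m],
                   expected, tolerance = 1e-12)
    }
  }
  # the mediating miRNA has the maximal S in the mediated pair's row
  med_row <- scan$s_matrix[paste(rownames(mrna$values)[1],
                                 rownames(lnc$values)[1], sep = "|"), ]
  expect_identical(names(which.max(med_row[1:2])), rownames(mir$values)[1])
  # zero-variance miRNA column is NA and excluded from triplets
  expect_true(all(is.na(scan$s_matrix[, 3])))
  expect_false(rownames(mir$values)[3] %in% scan$triplets$z_id)
})

test_that("independent miRNA yields near-zero sensitivity at large n", {
  set.seed(31)
  n <- 1000
  shared <- rnorm(n)
  mrna <- make_es(matrix(exp(1 + 0.15 * shared + 0.03 * rnorm(n)), 1, n), "mRNA")
  lnc <- make_es(matrix(exp(1 + 0.15 * shared + 0.03 * rnorm(n)), 1, n), "lncRNA")
  mir <- make_es(matrix(exp(2 + 0.05 * rnorm(n)), 1, n), "miRNA")
  pairs <- tibble::tibble(x_id = rownames(mrna$values),
                          y_id = rownames(lnc$values),
                          rho_xy = pearson_cor(mrna$values[1, ], lnc$values[1, ]))
  scan <- suppressMessages(triplet_scan(pairs, mrna, lnc, mir, s_threshold = 0.3))
  expect_lt(abs(scan$s_matrix[1, 1]), 0.05)
})

test_that("hypergeometric enrichment matches the exact combinatorial sum", {
  # index state giving N = 10 windows, K = 4 site occurrences, pair sample
  # n = 3 + 2 = 5 windows with k = 2 + 1 = 3 observed -> p = 66/252
  idx <- list(
    windows = tibble::tibble(transcript_id = c("x", "y", "rest"),
                             windows = c(3L, 2L, 5L)),
    counts = tibble::tibble(transcript_id = c("x", "y", "rest"),
                            mirna_id = "m", count = c(2L, 1L, 1L)),
    totals = tibble::tibble(mirna_id = "m", total_count = 4L),
    sites = tibble::tibble(mirna_id = "m", match_site = "AAAAAA")
  )
  class(idx) <- "seed_index"
  expect_equal(enrichment_test("x", "y", "m", idx), 66 / 252, tolerance = 1e-12)
  # k = 0 is certain
  idx$counts$count <- c(0L, 0L, 4L)
  expect_equal(enrichment_test("x", "y", "m", idx), 1)
})

test_that("enrichment equals brute-force enumeration on random instances", {
  set.seed(13)
  for (i in seq_len(100)) {
    N <- sample(5:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k_max <- min(K, n)
    k <- sample(0:k_max, 1)
    idx <- list(
      windows = tibble::tibble(transcript_id = c("x", "y", "bg"),
                               windows = c(n, 0L, N - n)),
      counts = tibble::tibble(transcript_id = c("x", "y", "bg"),
                              mirna_id = "m", count = c(k, 0L, K - k)),
      totals = tibble::tibble(mirna_id = "m", total_count = K),
      sites = tibble::tibble(mirna_id = "m", match_site = "AAAAAA")
    )
    class(idx) <- "seed_index"
    if (K - k > N - n) next  # infeasible configuration
    expect_equal(enrichment_test("x", "y", "m", idx),
                 brute_hyper_upper(k, N, K, n), tolerance = 1e-12)
  }
})

test_that("enrichment p is monotone non-increasing in the observed count", {
  N <- 60; K <- 12; n <- 15
  ps <- vapply(0:min(K, n), function(k) brute_hyper_upper(k, N, K, n), numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  # and the implementation tracks the same monotonicity
  mk_idx <- function(k) {
    idx <- list(
      windows = tibble::tibble(transcript_id = c("x", "y", "bg"),
                               windows = c(10L, 5L, N - 15L)),
      counts = tibble::tibble(transcript_id = c("x", "y", "bg"),
                              mirna_id = "m", count = c(k, 0L, K - k)),
      totals = tibble::tibble(mirna_id = "m", total_count = K),
      sites = tibble::tibble(mirna_id = "m", match_site = "AAAAAA")
    )
    class(idx) <- "seed_index"
    idx
  }
  imp <- vapply(0:12, function(k) enrichment_test("x", "y", "m", mk_idx(k)),
                numeric(1))
  expect_true(all(diff(imp) <= 1e-15))
})

test_that("corrupt index states are rejected", {
  idx <- list(
    windows = tibble::tibble(transcript_id = c("x", "y"), windows = c(2L, 1L)),
    counts = tibble::tibble(transcript_id = c("x", "y"), mirna_id = "m",
                            count = c(5L, 0L)),
    totals = tibble::tibble(mirna_id = "m", total_count = 5L),
    sites = tibble::tibble(mirna_id = "m", match_site = "AAAAAA")
  )
  class(idx) <- "seed_index"
  expect_error(enrichment_test("x", "y", "m", idx), "Corrupt index")
  expect_error(enrichment_test("x", "zzz", "m", idx), "missing from index")
})

test_that("confounder-only data keeps sensitivity near zero at n = 72", {
  fracs <- vapply(seq_len(20), function(s) {
    ds <- simulate_sponge_dataset(sponge_sim_params(
      n_sponge_triplets = 0, n_confounded_pairs = 15, n_background = 10,
      seed = 100 + s
    ))
    mrna <- filter_condition(ds$mrna, "normal")
    lnc <- filter_condition(ds$lncrna, "normal")
    mir <- filter_condition(ds$mirna, "normal")
    pairs <- ds$truth$confounded %>%
      dplyr::mutate(rho_xy = purrr::map2_dbl(
        x_id, y_id, ~ pearson_cor(mrna$values[.x, ], lnc$values[.y, ])
      ))
    scan <- suppressMessages(triplet_scan(pairs, mrna, lnc, mir))
    mean(abs(scan$s_matrix) < 0.1, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(fracs), 0.99)
})
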