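fake_triplets <- function(...) {
  rows <- list(...)
  tibble::tibble(
    x_id = purrr::map_chr(rows, 1),
    y_id = purrr::map_chr(rows, 2),
    z_id = purrr::map_chr(rows, 3),
    rho_xy = 0.9, rho_xz = -0.8, rho_zy = -0.8,
    rho_xy_given_z = 0.5, sensitivity = 0.4,
    site_count_x = purrr::map_dbl(rows, 4),
    site_count_y = purrr::map_dbl(rows, 5),
    enrichment_p = purrr::map_dbl(rows, 6)
  )
}

test_that("network building applies the strict enrichment and site conditions", {
  tr <- fake_triplets(
    list("A", "L1", "m1", 1, 2, 0.001),
    list("B", "L1", "m1", 1, 1, 0.005),
    list("C", "L1", "m1", 1, 1, 0.01),   # p = alpha exactly -> excluded
    list("D", "L1", "m1", 0, 3, 0.001)   # no site in X -> excluded
  )
  net <- suppressMessages(build_network(tr))
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  deg <- node_degrees(net)
  expect_equal(deg$degree[deg$id == "L1"], 2L)
})

test_that("parallel edges for one pair with two miRNAs are both kept", {
  tr <- fake_triplets(
    list("A", "L1", "m1", 1, 1, 0.001),
    list("A", "L1", "m2", 2, 1, 0.002)
  )
  net <- suppressMessages(build_network(tr))
  expect_equal(nrow(net$edges), 2L)
  deg <- node_degrees(net)
  expect_equal(deg$degree[deg$id == "A"], 2L)
  nb <- neighborhood(net, "A")
  expect_equal(nrow(nb$edges), 2L)                       # 2 parallel edges
  expect_equal(nrow(nb$nodes), 2L)                       # but 1 neighbour
})

test_that("self-pair triplets are rejected with a warning", {
  tr <- fake_triplets(list("A", "A", "m1", 1, 1, 0.001),
                      list("A", "L1", "m1", 1, 1, 0.001))
  expect_warning(net <- suppressMessages(build_network(tr)), "self-pair")
  expect_equal(nrow(net$edges), 1L)
})

test_that("degree sum equals twice the edge count and build is order-invariant", {
  set.seed(17)
  rows <- lapply(seq_len(30), function(i) {
    list(sample(LETTERS[1:8], 1), sample(c("L1", "L2", "L3"), 1),
         sample(c("m1", "m2", "m3", "m4"), 1), 1, 1, runif(1, 0, 0.02))
  })
  tr <- do.call(fake_triplets, rows) %>%
    dplyr::distinct(x_id, y_id, z_id, .keep_all = TRUE)
  net <- suppressMessages(build_network(tr))
  expect_equal(sum(node_degrees(net)$degree), 2L * nrow(net$edges))
  perm <- tr[sample(nrow(tr)), ]
  net2 <- suppressMessages(build_network(perm))
  expect_identical(net$edges, net2$edges)
  expect_identical(net$nodes, net2$nodes)
  # relaxing the enrichment cut never removes edges
  loose <- suppressMessages(build_network(tr, enrichment_alpha = 1))
  expect_gte(nrow(loose$edges), nrow(net$edges))
})

test_that("hub ranking is by degree then lexicographic id", {
  tr <- fake_triplets(
    list("A", "Hub", "m1", 1, 1, 0.001), list("B", "Hub", "m1", 1, 1, 0.001),
    list("C", "Hub", "m1", 1, 1, 0.001), list("D", "Hub", "m1", 1, 1, 0.001),
    list("E", "Hub", "m1", 1, 1, 0.001)
  )
  net <- suppressMessages(build_network(tr))
  hubs <- top_hubs(net, 3)
  expect_identical(hubs$id[1], "Hub")
  expect_equal(hubs$degree[1], 5L)
  expect_identical(hubs$id[2:3], c("A", "B"))  # tie broken lexicographically
  expect_error(top_hubs(net, 0), "positive")
})

test_that("miRNA edge fractions normalise over the node's degree", {
  tr <- fake_triplets(
    list("A", "L", "m1", 1, 1, 1e-3), list("B", "L", "m1", 1, 1, 1e-3),
    list("C", "L", "m1", 1, 1, 1e-3), list("D", "L", "m1", 1, 1, 1e-3),
    list("E", "L", "m2", 1, 1, 1e-3)
  )
  net <- suppressMessages(build_network(tr))
  expect_equal(mirna_edge_fraction(net, "L", "m1"), 0.8)
  expect_equal(mirna_edge_fraction(net, "L", c("m1", "m2")), 1)
  expect_equal(mirna_edge_fraction(net, "L", character(0)), 0)
  expect_error(mirna_edge_fraction(net, "nope", "m1"), "not in network")
})

test_that("network comparison reports Jaccard overlap and degree deltas", {
  tr_a <- fake_triplets(list("A", "L1", "m1", 1, 1, 1e-3),
                        list("B", "L1", "m1", 1, 1, 1e-3))
  tr_b <- fake_triplets(list("C", "L2", "m2", 1, 1, 1e-3))
  net_a <- suppressMessages(build_network(tr_a))
  net_b <- suppressMessages(build_network(tr_b))
  same <- compare_networks(net_a, net_a)
  expect_equal(same$summary$node_jaccard, 1)
  expect_equal(same$summary$edge_jaccard, 1)
  expect_true(all(same$degree_delta$delta == 0))
  disjoint <- compare_networks(net_a, net_b)
  expect_equal(disjoint$summary$edge_jaccard, 0)
  expect_equal(disjoint$summary$nodes_shared, 0L)
})

test_that("edge-list TSV round-trips and empty networks export header-only", {
  tr <- fake_triplets(list("A", "L1", "m1", 1, 1, 1e-3),
                      list("A", "L1", "m2", 1, 1, 1e-3),
                      list("B", "L2", "m1", 1, 1, 1e-3))
  net <- suppressMessages(build_network(tr))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, path, "tsv")
  back <- read_network_tsv(path)
  expect_identical(back$edges, net$edges)
  expect_identical(back$nodes, net$nodes)

  empty <- mmi_network(tibble::tibble(id = character(), role = character()),
                       tibble::tibble(node_a = character(),
                                      node_b = character(),
                                      mirna_id = character()))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, p2, "tsv")
  expect_equal(length(readLines(p2)), 1L)
})

test_that("GraphML export is valid XML and igraph-readable with attributes", {
  tr <- fake_triplets(list("A", "L1", "m1", 1, 1, 1e-3),
                      list("B", "L1", "m2", 1, 1, 1e-3))
  net <- suppressMessages(build_network(tr))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path, "graphml")
  doc <- xml2::read_xml(path)  # independent parser: must be well-formed
  expect_identical(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  expect_setequal(igraph::edge_attr(g, "mirna_id"), c("m1", "m2"))
  expect_error(export_network(net, path, "dot"), "arg")
})

test_that("a planted super-sponge lncRNA emerges as the top hub", {
  hits <- vapply(seq_len(20), function(s) {
    ds <- simulate_sponge_dataset(sponge_sim_params(
      n_sponge_triplets = 12, n_confounded_pairs = 10, n_background = 10,
      super_sponge = TRUE, seed = 400 + s
    ))
    cfg <- pipeline_config(input_dir = NULL, seed = 400 + s)
    mrna <- filter_condition(ds$mrna, "normal")
    lnc <- filter_condition(ds$lncrna, "normal")
    mir <- filter_condition(ds$mirna, "normal")
    pairs <- suppressMessages(suppressWarnings(select_top_pairs(mrna, lnc)))
    scan <- suppressMessages(triplet_scan(pairs, mrna, lnc, mir))
    idx <- build_seed_index(dplyr::bind_rows(ds$utr_sequences, ds$lnc_sequences),
                            ds$mirnas)
    net <- suppressMessages(build_network(add_enrichment(scan$triplets, idx)))
    top_hubs(net, 1)$id == "lncRNA_001"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("switching mediation off in cancer rewires the planted hub most", {
  ds <- simulate_sponge_dataset(sponge_sim_params(
    n_sponge_triplets = 12, n_confounded_pairs = 10, n_background = 10,
    super_sponge = TRUE, cancer_mediation = FALSE, seed = 99
  ))
  idx <- build_seed_index(dplyr::bind_rows(ds$utr_sequences, ds$lnc_sequences),
                          ds$mirnas)
  infer_one <- function(cond) {
    mrna <- filter_condition(ds$mrna, cond)
    lnc <- filter_condition(ds$lncrna, cond)
    mir <- filter_condition(ds$mirna, cond)
    pairs <- suppressMessages(suppressWarnings(select_top_pairs(mrna, lnc)))
    scan <- suppressMessages(triplet_scan(pairs, mrna, lnc, mir))
    suppressMessages(build_network(add_enrichment(scan$triplets, idx)))
  }
  net_n <- infer_one("normal")
  cmp_ok <- tryCatch({
    net_c <- infer_one("cancer")
    cmp <- compare_networks(net_n, net_c)
    cmp$degree_delta$id[1]
  }, spongenet_empty = function(e) {
    # cancer network empty: the hub loses its entire degree
    empty <- mmi_network(tibble::tibble(id = character(), role = character()),
                         tibble::tibble(node_a = character(),
                                        node_b = character(),
                                        mirna_id = character()))
    compare_networks(net_n, empty)$degree_delta$id[1]
  })
  expect_identical(cmp_ok, "lncRNA_001")
})
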