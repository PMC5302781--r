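#' miRNA-mediated interaction (MMI) network
#'
#' The sponge network is an undirected multigraph: nodes are mRNAs and
#' lncRNAs, and each edge is labelled by the miRNA mediating the pair's
#' co-expression. Parallel edges between one pair (different miRNAs) are kept
#' distinct, and a node's degree counts them separately.
#'
#' @param nodes tibble with `id`, `role`.
#' @param edges tibble with `node_a`, `node_b`, `mirna_id`.
#' @param provenance named list of thresholds used at build time.
#' @return An object of class `mmi_network`.
#' @export
mmi_network <- function(nodes, edges, provenance = list()) {
  nodes <- as_tibble(nodes) %>% distinct(.data$id, .keep_all = TRUE)
  edges <- as_tibble(edges)
  if (nrow(edges) && anyDuplicated(edges[, c("node_a", "node_b", "mirna_id")])) {
    abort("At most one edge per (pair, miRNA) is allowed.")
  }
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "mmi_network")
}

#' @export
print.mmi_network <- function(x, ...) {
  cat("<mmi_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(%d mRNA, %d lncRNA; %d distinct miRNA labels)\n",
              sum(x$nodes$role == "mRNA"), sum(x$nodes$role == "lncRNA"),
              dplyr::n_distinct(x$edges$mirna_id)))
  invisible(x)
}

#' @method tidy mmi_network
#' @export
tidy.mmi_network <- function(x, ...) x$edges

#' @method glance mmi_network
#' @export
glance.mmi_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_mrna = sum(x$nodes$role == "mRNA"),
    n_lncrna = sum(x$nodes$role == "lncRNA"),
    n_mirna_labels = dplyr::n_distinct(x$edges$mirna_id)
  )
}

#' Build the MMI network from enrichment-annotated triplets
#'
#' One edge per triplet that passes the enrichment cut (`enrichment_p <
#' enrichment_alpha`, strict) and whose two transcripts each carry at least
#' one site of the shared miRNA. Triplets pairing a node with itself are
#' rejected with a warning. The sensitivity and pair-correlation conditions
#' were already enforced upstream; the thresholds travel in `provenance`.
#'
#' @param triplets tibble from [add_enrichment()] (columns `x_id`, `y_id`,
#'   `z_id`, `site_count_x`, `site_count_y`, `enrichment_p`).
#' @param enrichment_alpha enrichment cut (default 0.01, strict `<`).
#' @param provenance optional named list of upstream thresholds to record.
#' @return An [mmi_network()].
#' @export
build_network <- function(triplets, enrichment_alpha = 0.01, provenance = list()) {
  self <- triplets$x_id == triplets$y_id
  if (any(self)) {
    warn(sprintf("Rejected %d self-pair triplet(s).", sum(self)))
    triplets <- triplets[!self, , drop = FALSE]
  }
  passing <- triplets %>%
    filter(.data$enrichment_p < enrichment_alpha,
           .data$site_count_x >= 1, .data$site_count_y >= 1) %>%
    distinct(.data$x_id, .data$y_id, .data$z_id, .keep_all = TRUE) %>%
    arrange(.data$x_id, .data$y_id, .data$z_id)
  inform(sprintf(
    "enrichment filter (p < %g, shared sites): retained %d / %d triplets",
    enrichment_alpha, nrow(passing), nrow(triplets)
  ))
  nodes <- bind_rows(
    tibble(id = passing$x_id, role = "mRNA"),
    tibble(id = passing$y_id, role = "lncRNA")
  ) %>% distinct(.data$id, .keep_all = TRUE) %>% arrange(.data$id)
  edges <- passing %>%
    select(node_a = "x_id", node_b = "y_id", mirna_id = "z_id")
  mmi_network(nodes, edges,
              provenance = c(provenance, list(enrichment_alpha = enrichment_alpha)))
}

#' Node degrees (parallel edges counted separately)
#'
#' @param net an [mmi_network()].
#' @return Tibble `id`, `role`, `degree`, covering every node (degree 0 kept).
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "mmi_network"))
  inc <- c(net$edges$node_a, net$edges$node_b)
  deg <- table(factor(inc, levels = net$nodes$id))
  net$nodes %>% mutate(degree = as.integer(deg[.data$id]))
}

#' Top hub nodes by degree
#'
#' @param net an [mmi_network()] with at least one node.
#' @param k number of hubs to return (> 0).
#' @return Tibble `id`, `role`, `degree`, sorted by degree descending, ties
#'   broken lexicographically by id.
#' @export
top_hubs <- function(net, k) {
  if (!is.numeric(k) || k <= 0) abort("`k` must be a positive integer.")
  if (nrow(net$nodes) == 0) abort("Empty network.")
  node_degrees(net) %>%
    arrange(desc(.data$degree), .data$id) %>%
    head(k)
}

#' Fraction of a node's edges mediated by a miRNA set
#'
#' @param net an [mmi_network()].
#' @param node node id present in the network.
#' @param mirna_set character vector of miRNA ids (e.g. one family).
#' @return The fraction of the node's incident edges whose label is in
#'   `mirna_set`; `NA_real_` with a warning for an isolated node.
#' @export
mirna_edge_fraction <- function(net, node, mirna_set) {
  stopifnot(inherits(net, "mmi_network"))
  if (!node %in% net$nodes$id) abort(paste0("Node not in network: ", node))
  inc <- net$edges %>% filter(.data$node_a == node | .data$node_b == node)
  if (nrow(inc) == 0) {
    warn("Node has degree 0: fraction undefined.")
    return(NA_real_)
  }
  mean(inc$mirna_id %in% mirna_set)
}

#' Star neighbourhood of a node
#'
#' @param net an [mmi_network()].
#' @param node node id present in the network.
#' @return An [mmi_network()] induced by the node, its incident edges and its
#'   neighbours, with `n_mrna_neighbors` recorded in provenance.
#' @export
neighborhood <- function(net, node) {
  stopifnot(inherits(net, "mmi_network"))
  if (!node %in% net$nodes$id) abort(paste0("Node not in network: ", node))
  inc <- net$edges %>% filter(.data$node_a == node | .data$node_b == node)
  ids <- union(node, union(inc$node_a, inc$node_b))
  nodes <- net$nodes %>% filter(.data$id %in% ids)
  n_mrna_nb <- nodes %>%
    filter(.data$id != node, .data$role == "mRNA") %>%
    nrow()
  mmi_network(nodes, inc,
              provenance = c(net$provenance,
                             list(center = node, n_mrna_neighbors = n_mrna_nb)))
}

#' Compare two MMI networks (rewiring summary)
#'
#' @param net_a,net_b [mmi_network()]s, e.g. normal- and cancer-condition.
#' @return List with `summary` (one-row tibble: shared/unique node and
#'   (pair, miRNA) edge counts and both Jaccard indices) and `degree_delta`
#'   (tibble `id`, `degree_a`, `degree_b`, `delta` over the node union).
#' @export
compare_networks <- function(net_a, net_b) {
  key <- function(net) {
    if (nrow(net$edges) == 0) return(character(0))
    # undirected: canonicalise endpoint order
    a <- pmin(net$edges$node_a, net$edges$node_b)
    b <- pmax(net$edges$node_a, net$edges$node_b)
    paste(a, b, net$edges$mirna_id, sep = "\t")
  }
  ea <- key(net_a); eb <- key(net_b)
  na <- net_a$nodes$id; nb <- net_b$nodes$id
  jacc <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) return(NA_real_)
    length(intersect(a, b)) / u
  }
  deg_a <- node_degrees(net_a); deg_b <- node_degrees(net_b)
  degree_delta <- tibble(id = union(na, nb)) %>%
    left_join(deg_a %>% select("id", degree_a = "degree"), by = "id") %>%
    left_join(deg_b %>% select("id", degree_b = "degree"), by = "id") %>%
    mutate(
      degree_a = dplyr::coalesce(.data$degree_a, 0L),
      degree_b = dplyr::coalesce(.data$degree_b, 0L),
      delta = .data$degree_b - .data$degree_a
    ) %>%
    arrange(desc(abs(.data$delta)))
  list(
    summary = tibble(
      nodes_shared = length(intersect(na, nb)),
      nodes_only_a = length(setdiff(na, nb)),
      nodes_only_b = length(setdiff(nb, na)),
      edges_shared = length(intersect(ea, eb)),
      edges_only_a = length(setdiff(ea, eb)),
      edges_only_b = length(setdiff(eb, ea)),
      node_jaccard = jacc(na, nb),
      edge_jaccard = jacc(ea, eb)
    ),
    degree_delta = degree_delta
  )
}

#' Export an MMI network
#'
#' Edge-list TSV (`node_a`, `node_b`, `mirna_id`, `role_a`, `role_b`) or
#' GraphML (via igraph, miRNA as edge attribute, role as node attribute).
#'
#' @param net an [mmi_network()].
#' @param path output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path` invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "mmi_network"))
  format <- match.arg(format)
  if (format == "tsv") {
    role_of <- setNames(net$nodes$role, net$nodes$id)
    out <- net$edges %>%
      mutate(role_a = unname(role_of[.data$node_a]),
             role_b = unname(role_of[.data$node_b]))
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert an MMI network to igraph
#'
#' @param net an [mmi_network()].
#' @return An undirected igraph multigraph with node attribute `role` and
#'   edge attribute `mirna_id`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mmi_network"))
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Re-import an edge-list TSV written by [export_network()]
#'
#' @param path TSV path.
#' @return An [mmi_network()].
#' @export
read_network_tsv <- function(path) {
  tbl <- readr::read_tsv(path, col_types = "ccccc", progress = FALSE)
  nodes <- bind_rows(
    tibble(id = tbl$node_a, role = tbl$role_a),
    tibble(id = tbl$node_b, role = tbl$role_b)
  ) %>% distinct(.data$id, .keep_all = TRUE) %>% arrange(.data$id)
  mmi_network(nodes, tbl %>% select("node_a", "node_b", "mirna_id"))
}

#' Machine-readable network summary
#'
#' @param net an [mmi_network()].
#' @param path output JSON path.
#' @param k number of top hubs to include.
#' @return `path` invisibly.
#' @export
write_network_summary <- function(net, path, k = 10) {
  per_mirna <- net$edges %>%
    group_by(.data$mirna_id) %>%
    summarise(n_edges = n(), .groups = "drop") %>%
    arrange(desc(.data$n_edges))
  hubs <- if (nrow(net$nodes)) top_hubs(net, min(k, nrow(net$nodes))) else tibble()
  jsonlite::write_json(
    list(
      counts = as.list(glance(net)),
      provenance = net$provenance,
      top_hubs = hubs,
      per_mirna_edges = per_mirna
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
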