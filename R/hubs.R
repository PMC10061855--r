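#' Read an undirected interaction edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b` and optionally `score`
#'   (edge confidence). Self-loops and parallel edges are collapsed.
#' @param min_score Optional confidence cutoff applied before scoring.
#' @return Tibble: gene_a, gene_b (, score), one row per undirected edge.
#' @export
read_network <- function(path, min_score = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(df, c("gene_a", "gene_b"), "edge list")
  if (!is.null(min_score)) {
    assert_columns(df, "score", "edge list")
    df <- filter(df, .data$score >= min_score)
  }
  df <- filter(df, .data$gene_a != .data$gene_b)
  pair <- tibble(gene_a = pmin(df$gene_a, df$gene_b),
                 gene_b = pmax(df$gene_a, df$gene_b))
  if ("score" %in% names(df)) pair$score <- df$score
  distinct(pair, .data$gene_a, .data$gene_b, .keep_all = TRUE)
}

edges_to_graph <- function(edges) {
  assert_columns(edges, c("gene_a", "gene_b"), "edge list")
  g <- igraph::graph_from_data_frame(
    edges[c("gene_a", "gene_b")], directed = FALSE)
  igraph::simplify(g)
}

#' Maximal clique centrality (MCC) and degree hub scores
#'
#' MCC(v) = sum over the maximal cliques C containing v of (|C| - 1)!, the
#' flagship hub metric of the cytoHubba family; isolated nodes score 0. The
#' graph's maximal cliques are enumerated exactly (Bron-Kerbosch with
#' pivoting, via igraph), so the computation is refused above `max_nodes`
#' nodes — prune the network (e.g. by edge confidence) first.
#'
#' @param edges Edge-list tibble (`gene_a`, `gene_b`), e.g. from
#'   [read_network()].
#' @param nodes Optional character vector of nodes to score (defaults to the
#'   nodes in the edge list; include isolated genes by listing them here).
#' @param max_nodes Refuse graphs larger than this (default 5000).
#' @return A `dm_hubs` tibble: gene, degree, mcc, rank_degree, rank_mcc
#'   (ranks dense, ties sharing a rank).
#' @examples
#' tri <- tibble::tibble(gene_a = c("a", "b", "a"), gene_b = c("b", "c", "c"))
#' mcc_score(tri)
#' @export
mcc_score <- function(edges, nodes = NULL, max_nodes = 5000) {
  g <- edges_to_graph(edges)
  if (igraph::vcount(g) > max_nodes) {
    abort(sprintf(
      "network has %d nodes (> max_nodes = %d); filter edges (e.g. by confidence score) before hub scoring",
      igraph::vcount(g), max_nodes))
  }
  all_nodes <- union(igraph::V(g)$name, nodes)
  mcc <- setNames(numeric(length(all_nodes)), all_nodes)
  deg <- setNames(numeric(length(all_nodes)), all_nodes)
  if (igraph::vcount(g) > 0) {
    deg[igraph::V(g)$name] <- igraph::degree(g)
    cliques <- igraph::max_cliques(g, min = 2)
    for (cl in cliques) {
      w <- factorial(length(cl) - 1)
      ids <- igraph::V(g)$name[as.integer(cl)]
      mcc[ids] <- mcc[ids] + w
    }
  }
  out <- tibble(gene = all_nodes, degree = as.integer(unname(deg)),
                mcc = unname(mcc)) %>%
    mutate(rank_degree = dplyr::dense_rank(dplyr::desc(.data$degree)),
           rank_mcc = dplyr::dense_rank(dplyr::desc(.data$mcc))) %>%
    arrange(dplyr::desc(.data$mcc), dplyr::desc(.data$degree), .data$gene)
  structure(out, class = c("dm_hubs", class(out)))
}

#' Top-ranked hub genes
#'
#' @param scores `dm_hubs` tibble from [mcc_score()].
#' @param k Number of hubs to return (default 5, the usual reporting depth).
#' @param metric `"mcc"` or `"degree"`.
#' @return The top `k` rows, descending by the metric with ties broken
#'   lexicographically by gene ID; all rows (with a warning) when `k`
#'   exceeds the node count.
#' @export
top_hubs <- function(scores, k = 5, metric = c("mcc", "degree")) {
  metric <- match.arg(metric)
  if (k < 1) abort("k must be >= 1")
  if (k > nrow(scores)) {
    warn(sprintf("k = %d exceeds the %d scored nodes: returning all", k,
                 nrow(scores)))
    k <- nrow(scores)
  }
  scores %>%
    arrange(dplyr::desc(.data[[metric]]), .data$gene) %>%
    head(k)
}

#' Export a network in SIF format
#'
#' Simple-interaction format (`gene_a <tab> pp <tab> gene_b`) readable by
#' Cytoscape.
#'
#' @param edges Edge-list tibble (`gene_a`, `gene_b`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  readr::write_tsv(tibble(gene_a = edges$gene_a, interaction = "pp",
                          gene_b = edges$gene_b),
                   path, col_names = FALSE)
  invisible(path)
}
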