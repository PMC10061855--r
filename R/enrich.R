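#' Upper-tail hypergeometric test
#'
#' P(X >= k) when drawing `n` genes from a universe of `N` that contains `K`
#' genes carrying the term — the over-representation p-value used for GO/KEGG
#' style enrichment.
#'
#' @param k Hits in the query set.
#' @param n Query-set size.
#' @param K Term size in the background.
#' @param N Background-universe size.
#' @return The p-value (vectorised over its arguments).
#' @examples
#' hypergeom_test(3, 5, 4, 20)
#' @export
hypergeom_test <- function(k, n, K, N) {
  ok <- k >= 0 & n >= k & K >= k & N >= n & N >= K
  if (any(!ok)) abort("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read a gene-to-term annotation table
#'
#' @param path TSV with columns `gene`, `term_id` and optionally `term_name`,
#'   `namespace`.
#' @return Tibble with those columns (`term_name`/`namespace` filled with NA
#'   when absent).
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(ann, c("gene", "term_id"), "annotation table")
  if (!"term_name" %in% names(ann)) ann$term_name <- NA_character_
  if (!"namespace" %in% names(ann)) ann$namespace <- NA_character_
  distinct(ann, .data$gene, .data$term_id, .keep_all = TRUE)
}

#' Hypergeometric term over-representation
#'
#' Tests every annotated term with at least one query hit for
#' over-representation of the query gene set against a background universe,
#' BH-adjusts across tested terms and sorts by adjusted p. Query genes
#' outside the background are dropped with a warning; terms smaller than
#' `min_term_size` in the background are excluded (noise control). Term
#' hierarchies are not traversed — each term is tested on its direct
#' annotations only.
#'
#' @param query Character vector of gene IDs.
#' @param annotation Tibble from [read_annotation()] (columns `gene`,
#'   `term_id`, optionally `term_name`, `namespace`).
#' @param background Character vector: the gene universe (typically all genes
#'   in the count matrix). Annotations outside it are ignored.
#' @param alpha Significance threshold recorded on the result.
#' @param min_term_size Minimum background term size (default 2).
#' @return A `dm_enrichment` tibble: term_id, term_name, namespace, k, n, K,
#'   N, fold_enrichment = (k/n)/(K/N), pvalue, padj, significant.
#' @export
enrich <- function(query, annotation, background, alpha = 0.05,
                   min_term_size = 2) {
  background <- unique(background)
  if (length(background) == 0) abort("empty background universe")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the background dropped",
                 length(outside)))
    query <- setdiff(query, outside)
  }
  ann <- filter(as_tibble(annotation), .data$gene %in% background)
  N <- length(background)
  n <- length(query)

  terms <- ann %>%
    group_by(.data$term_id) %>%
    summarise(term_name = dplyr::first(.data$term_name),
              namespace = dplyr::first(.data$namespace),
              K = dplyr::n_distinct(.data$gene),
              k = dplyr::n_distinct(intersect(.data$gene, query)),
              .groups = "drop") %>%
    filter(.data$K >= min_term_size, .data$k >= 1)

  if (nrow(terms) == 0) {
    out <- tibble(term_id = character(0), term_name = character(0),
                  namespace = character(0), k = integer(0), n = integer(0),
                  K = integer(0), N = integer(0),
                  fold_enrichment = numeric(0), pvalue = numeric(0),
                  padj = numeric(0), significant = logical(0))
    return(structure(out, class = c("dm_enrichment", class(out)),
                     alpha = alpha))
  }

  out <- terms %>%
    mutate(n = n, N = N,
           fold_enrichment = (.data$k / .data$n) / (.data$K / .data$N),
           pvalue = hypergeom_test(.data$k, .data$n, .data$K, .data$N),
           padj = bh_adjust(.data$pvalue),
           significant = .data$padj < alpha) %>%
    arrange(.data$padj, .data$pvalue, .data$term_id) %>%
    select("term_id", "term_name", "namespace", "k", "n", "K", "N",
           "fold_enrichment", "pvalue", "padj", "significant")
  structure(out, class = c("dm_enrichment", class(out)), alpha = alpha)
}
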