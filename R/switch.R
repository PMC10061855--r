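#' Split a gene set into regulatory and functional genes
#'
#' Partitions drought-memory genes (DMGs) into regulatory DMGs (those on a
#' transcription factor / transcription regulator list) and functional DMGs
#' (everything else). Regulators not present in the DMG set are ignored with
#' a warning.
#'
#' @param dmgs Character vector of DMG IDs.
#' @param regulators Character vector of TF/TR gene IDs.
#' @return List with `regulatory` and `functional` character vectors (a
#'   disjoint partition of `dmgs`).
#' @export
split_regulatory <- function(dmgs, regulators) {
  dmgs <- unique(dmgs)
  regulators <- unique(regulators)
  absent <- setdiff(regulators, dmgs)
  if (length(absent) > 0) {
    warn(sprintf("%d regulator(s) not in the DMG set ignored", length(absent)))
  }
  list(regulatory = intersect(dmgs, regulators),
       functional = setdiff(dmgs, regulators))
}

#' Read a regulator (TF/TR) gene list
#'
#' @param path Text file, one gene ID per line (blank lines and `#` comments
#'   skipped).
#' @return Character vector of gene IDs.
#' @export
read_regulators <- function(path) {
  x <- stringr::str_trim(readr::read_lines(path))
  unique(x[x != "" & !startsWith(x, "#")])
}

#' Signed TF-target Pearson co-expression
#'
#' Pearson correlation between every regulator (TF) profile and every target
#' profile over the columns of an expression matrix (typically
#' log2(FPKM + 1) over one ecotype's samples; see [log_fpkm_matrix()]).
#' Two-sided p-values come from the t transform
#' `t = r * sqrt(m - 2) / sqrt(1 - r^2)` with `m - 2` degrees of freedom
#' (m = number of samples). Genes constant across samples have undefined r
#' and are skipped with a warning.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns (>= 3
#'   samples).
#' @param tfs Character vector of regulator gene IDs (rows of `expr`).
#' @param targets Character vector of target gene IDs (rows of `expr`).
#' @return Tibble of class `dm_edges`: tf, target, r, pvalue, sign
#'   (`"+"`/`"-"`); one row per (tf, target) pair with defined r, tf-target
#'   self-pairs excluded.
#' @export
correlate <- function(expr, tfs, targets) {
  if (!is.matrix(expr)) abort("expr must be a numeric matrix (genes x samples)")
  m <- ncol(expr)
  if (m < 3) abort("need >= 3 samples to correlate")
  tfs <- intersect(unique(tfs), rownames(expr))
  targets <- intersect(unique(targets), rownames(expr))
  if (length(tfs) == 0 || length(targets) == 0) {
    return(structure(tibble(tf = character(0), target = character(0),
                            r = numeric(0), pvalue = numeric(0),
                            sign = character(0)),
                     class = c("dm_edges", class(tibble()))))
  }
  keep_var <- function(g) apply(expr[g, , drop = FALSE], 1, sd) > 0
  const_tf <- tfs[!keep_var(tfs)]
  const_tg <- targets[!keep_var(targets)]
  if (length(const_tf) + length(const_tg) > 0) {
    warn(sprintf("%d gene(s) constant across samples skipped (r undefined)",
                 length(unique(c(const_tf, const_tg)))))
  }
  tfs <- setdiff(tfs, const_tf)
  targets <- setdiff(targets, const_tg)

  r <- cor(t(expr[tfs, , drop = FALSE]), t(expr[targets, , drop = FALSE]))
  out <- as_tibble(as.data.frame.table(r, stringsAsFactors = FALSE)) %>%
    rename(tf = "Var1", target = "Var2", r = "Freq") %>%
    filter(.data$tf != .data$target)
  rr <- pmin(pmax(out$r, -1), 1)
  tt <- rr * sqrt(m - 2) / sqrt(pmax(1 - rr^2, .Machine$double.eps))
  out$pvalue <- 2 * pt(-abs(tt), df = m - 2)
  out$pvalue[abs(rr) >= 1] <- 0
  out$sign <- ifelse(out$r >= 0, "+", "-")
  structure(out, class = c("dm_edges", class(out)), n_samples = m)
}

#' Filter co-expression edges at the switch thresholds
#'
#' Keeps edges with `|r| > r_min` and `p < p_max` (strict inequalities). The
#' magnitude of r is thresholded because switch detection needs both strong
#' positive and strong negative correlations.
#'
#' @param edges `dm_edges` tibble from [correlate()].
#' @param r_min Correlation magnitude threshold (default 0.9).
#' @param p_max P-value threshold (default 0.05).
#' @return Filtered `dm_edges` tibble.
#' @export
filter_edges <- function(edges, r_min = 0.9, p_max = 0.05) {
  out <- filter(as_tibble(edges), abs(.data$r) > r_min, .data$pvalue < p_max)
  structure(out, class = c("dm_edges", class(out)),
            n_samples = attr(edges, "n_samples"),
            r_min = r_min, p_max = p_max)
}

# canonical string form of a target's signed TF signature
signature_key <- function(tf, sign) {
  paste(sort(paste0(tf, ":", sign)), collapse = "|")
}

#' Detect TF "molecular switch" modules
#'
#' Groups functional genes by their exact signed TF signature (the map
#' tf -> correlation sign over the retained edges). Every signature group
#' whose regulator set contains at least `min_tfs_per_sign` positively and
#' `min_tfs_per_sign` negatively correlated TFs, and at least
#' `min_module_size` member genes, is reported as a switch module: a gene set
#' plausibly toggled between high and low expression by opposing regulators.
#' Exact-signature grouping makes modules disjoint in members by
#' construction; `relax_jaccard` optionally merges signatures whose TF sets
#' agree above a Jaccard threshold before grouping.
#'
#' @param edges Filtered `dm_edges` (see [filter_edges()]).
#' @param min_module_size Minimum member genes per module (default 5).
#' @param min_tfs_per_sign Minimum positive and minimum negative regulators
#'   (default 1 each).
#' @param relax_jaccard NULL (default, exact signatures) or a Jaccard
#'   threshold in (0, 1\] for merging near-identical signatures.
#' @return Tibble of class `dm_modules`: module, signature, positive_tfs,
#'   negative_tfs, members (list-columns), n_members; sorted by decreasing
#'   size. Zero rows when nothing qualifies.
#' @export
detect_switch_modules <- function(edges, min_module_size = 5,
                                  min_tfs_per_sign = 1,
                                  relax_jaccard = NULL) {
  edges <- as_tibble(edges)
  empty <- tibble(module = integer(0), signature = character(0),
                  positive_tfs = list(), negative_tfs = list(),
                  members = list(), n_members = integer(0))
  if (nrow(edges) == 0) {
    return(structure(empty, class = c("dm_modules", class(empty))))
  }

  sigs <- edges %>%
    group_by(.data$target) %>%
    summarise(signature = signature_key(.data$tf, .data$sign),
              .groups = "drop")

  if (!is.null(relax_jaccard)) {
    sigs$signature <- merge_signatures(sigs$signature, relax_jaccard)
  }

  groups <- sigs %>%
    group_by(.data$signature) %>%
    summarise(members = list(sort(.data$target)), .groups = "drop") %>%
    mutate(n_members = lengths(.data$members))

  parse_sig <- function(sig) {
    parts <- strsplit(sig, "|", fixed = TRUE)[[1]]
    tf <- sub(":[+-]$", "", parts)
    sign <- sub("^.*:", "", parts)
    list(pos = sort(tf[sign == "+"]), neg = sort(tf[sign == "-"]))
  }
  parsed <- purrr::map(groups$signature, parse_sig)
  groups$positive_tfs <- purrr::map(parsed, "pos")
  groups$negative_tfs <- purrr::map(parsed, "neg")

  out <- groups %>%
    filter(lengths(.data$positive_tfs) >= min_tfs_per_sign,
           lengths(.data$negative_tfs) >= min_tfs_per_sign,
           .data$n_members >= min_module_size) %>%
    arrange(dplyr::desc(.data$n_members), .data$signature) %>%
    mutate(module = dplyr::row_number()) %>%
    select("module", "signature", "positive_tfs", "negative_tfs",
           "members", "n_members")
  structure(out, class = c("dm_modules", class(out)))
}

# Merge signature keys whose TF sets (ignoring sign) have Jaccard similarity
# >= threshold; each signature adopts the key of the largest cluster member.
merge_signatures <- function(signatures, threshold) {
  uniq <- unique(signatures)
  tfsets <- lapply(uniq, function(s) {
    sub(":[+-]$", "", strsplit(s, "|", fixed = TRUE)[[1]])
  })
  k <- length(uniq)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      jac <- length(intersect(tfsets[[i]], tfsets[[j]])) /
        length(union(tfsets[[i]], tfsets[[j]]))
      if (jac >= threshold) parent[find(j)] <- find(i)
    }
  }
  root <- vapply(seq_len(k), find, integer(1))
  canon <- uniq[root[match(signatures, uniq)]]
  canon
}
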