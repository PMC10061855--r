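#' Read a count matrix and its sample design
#'
#' Loads a genes-by-samples TSV (first column gene IDs, header row of sample
#' IDs) together with a design table mapping each sample to ecotype,
#' treatment and replicate, and validates them jointly: no duplicate gene or
#' sample IDs, all counts non-negative integers, every sample covered by the
#' design.
#'
#' @param path Path to the count TSV.
#' @param design_path Path to the design TSV (columns `sample`, `ecotype`,
#'   `treatment`, `replicate`).
#' @param gene_col Name of the gene-ID column (default `"gene"`, the first
#'   column is used if absent).
#' @return A list of class `dm_counts`: `counts` (tibble) and `design`
#'   (tibble), row/column order preserved.
#' @export
read_counts <- function(path, design_path, gene_col = "gene") {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (!gene_col %in% names(counts)) gene_col <- names(counts)[1]
  counts <- rename(counts, gene = all_of(gene_col))
  design <- readr::read_tsv(design_path, show_col_types = FALSE)
  validate_counts(counts, design)
}

#' Validate a count table against its design
#'
#' @param counts Tibble: `gene` column plus one numeric column per sample.
#' @param design Tibble with columns `sample`, `ecotype`, `treatment`,
#'   `replicate`.
#' @return A list of class `dm_counts` (`counts`, `design`).
#' @export
validate_counts <- function(counts, design) {
  counts <- as_tibble(counts)
  design <- as_tibble(design)
  assert_columns(counts, "gene", "count table")
  assert_columns(design, c("sample", "ecotype", "treatment", "replicate"),
                 "design table")
  m <- counts_df_to_matrix(counts)
  if (anyDuplicated(colnames(m))) abort("duplicate sample IDs in count table")
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "count table has non-integer or negative cell(s), first at gene '%s', sample '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  missing <- setdiff(colnames(m), design$sample)
  if (length(missing) > 0) {
    abort(sprintf("sample(s) missing from design: %s",
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(design$sample)) abort("duplicate sample IDs in design")
  structure(list(counts = counts,
                 design = design[match(colnames(m), design$sample), ]),
            class = "dm_counts")
}

#' Write a count table to TSV
#'
#' @param counts Tibble with a `gene` column (e.g. `sim$counts`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' FPKM normalisation
#'
#' FPKM\[g, s\] = counts\[g, s\] / ((mapped_reads\[s\] / 1e6) *
#' length_kb\[g\]): fragments per kilobase of exon per million mapped reads.
#' By default the per-sample mapped-read total is the column sum of the count
#' matrix; an explicit named vector overrides it (e.g. totals that include
#' non-exonic reads).
#'
#' @param counts Tibble: `gene` column plus one column per sample.
#' @param gene_lengths Tibble with columns `gene` and `length_bp` (> 0).
#' @param mapped_reads `"column-sum"` (default) or a named numeric vector of
#'   per-sample mapped-read totals (> 0).
#' @return Tibble of the same shape as `counts` with FPKM values.
#' @examples
#' compute_fpkm(
#'   tibble::tibble(gene = "g1", s1 = 100),
#'   tibble::tibble(gene = "g1", length_bp = 1000),
#'   mapped_reads = c(s1 = 1e7))
#' @export
compute_fpkm <- function(counts, gene_lengths, mapped_reads = "column-sum") {
  m <- counts_df_to_matrix(counts)
  assert_columns(gene_lengths, c("gene", "length_bp"), "gene-length table")
  len <- gene_lengths$length_bp[match(rownames(m), gene_lengths$gene)]
  if (anyNA(len)) {
    abort(sprintf("gene(s) without a length: %s",
                  paste(head(rownames(m)[is.na(len)], 5), collapse = ", ")))
  }
  if (any(len <= 0)) abort("gene lengths must be positive")
  if (identical(mapped_reads, "column-sum")) {
    mapped_reads <- colSums(m)
  } else {
    missing <- setdiff(colnames(m), names(mapped_reads))
    if (length(missing) > 0) {
      abort(sprintf("mapped_reads missing sample(s): %s",
                    paste(missing, collapse = ", ")))
    }
    mapped_reads <- mapped_reads[colnames(m)]
  }
  if (any(mapped_reads <= 0)) abort("mapped_reads must be positive")
  fpkm <- sweep(m, 1, len / 1000, "/")
  fpkm <- sweep(fpkm, 2, mapped_reads / 1e6, "/")
  matrix_to_counts_df(fpkm)
}

#' Log2 expression matrix for co-expression analysis
#'
#' Convenience wrapper: log2(FPKM + pseudocount), returned as a numeric
#' matrix (genes x samples) ready for [correlate()].
#'
#' @inheritParams compute_fpkm
#' @param pseudocount Added before the log (default 1).
#' @return Numeric matrix, genes in rows.
#' @export
log_fpkm_matrix <- function(counts, gene_lengths,
                            mapped_reads = "column-sum", pseudocount = 1) {
  log2(counts_df_to_matrix(compute_fpkm(counts, gene_lengths, mapped_reads)) +
         pseudocount)
}

#' Replicate-quality diagnostics
#'
#' Thin reporting utility over standard decompositions: sample-level PCA of
#' log2(FPKM + 1) and the between-sample Pearson correlation matrix, used to
#' check that biological replicates group together.
#'
#' @inheritParams compute_fpkm
#' @param n_top Number of most-variable genes used for the PCA.
#' @return List with `pca` (tibble: sample, PC1, PC2, variance explained in
#'   `attr(, "var_explained")`) and `correlation` (sample correlation matrix).
#' @export
expression_diagnostics <- function(counts, gene_lengths,
                                   mapped_reads = "column-sum",
                                   n_top = 500) {
  lf <- log_fpkm_matrix(counts, gene_lengths, mapped_reads)
  rv <- apply(lf, 1, var)
  keep <- order(rv, decreasing = TRUE)[seq_len(min(n_top, nrow(lf)))]
  pc <- stats::prcomp(t(lf[keep, , drop = FALSE]), center = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  pca <- tibble(sample = colnames(lf),
                PC1 = pc$x[, 1],
                PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else 0)
  attr(pca, "var_explained") <- ve
  list(pca = pca, correlation = cor(lf))
}
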