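#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention used when
#' printing percentages in summary tables), unlike [round()], which rounds
#' half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(0.125 * 100 / 10, 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared validation helpers ----------------------------------------------

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# Convert a gene-by-sample tibble (first column = gene IDs) to a numeric
# matrix with gene rownames; the inverse of matrix_to_counts_df().
counts_df_to_matrix <- function(counts, gene_col = "gene") {
  assert_columns(counts, gene_col, "count table")
  genes <- counts[[gene_col]]
  if (anyDuplicated(genes)) {
    abort(sprintf("duplicate gene IDs in count table: %s",
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  m <- as.matrix(counts[setdiff(names(counts), gene_col)])
  if (!is.numeric(m)) abort("count table contains non-numeric cells")
  rownames(m) <- genes
  m
}

matrix_to_counts_df <- function(m, gene_col = "gene") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!gene_col := rownames(m)), out)
  out
}
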