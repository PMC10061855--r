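#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed the DESeq way: a geometric-mean
#' reference profile over genes expressed in every sample, then the median of
#' each sample's count/reference ratios. When no gene is expressed in all
#' samples, falls back to library-size factors (column sums scaled to
#' geometric mean 1) with a warning.
#'
#' @param counts Tibble with a `gene` column plus one numeric column per
#'   sample (or a numeric matrix).
#' @return Tibble: `sample`, `size_factor` (positive, identical columns get
#'   identical factors).
#' @export
estimate_size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts_df_to_matrix(counts)
  if (all(m == 0)) abort("all-zero count matrix: size factors undefined")
  expressed <- rowSums(m > 0) == ncol(m)
  if (!any(expressed)) {
    warn("no gene expressed in all samples: falling back to library-size factors")
    libs <- colSums(m)
    sf <- libs / exp(mean(log(libs)))
  } else {
    logref <- rowMeans(log(m[expressed, , drop = FALSE]))
    sf <- apply(m[expressed, , drop = FALSE], 2, function(cnt) {
      exp(median(log(cnt) - logref))
    })
  }
  tibble(sample = colnames(m), size_factor = unname(sf))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a validated wrapper over
#' [stats::p.adjust()]); monotone in the sorted order and capped at 1.
#'
#' @param pvalues Numeric vector in \[0, 1\] (NAs preserved).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

call_from_thresholds <- function(log2fc, padj, alpha, lfc_min) {
  dplyr::case_when(
    !is.na(padj) & padj < alpha & log2fc >= lfc_min ~ "up",
    !is.na(padj) & padj < alpha & log2fc <= -lfc_min ~ "down",
    TRUE ~ "ns")
}

#' Negative-binomial Wald test for one pairwise contrast
#'
#' An internal NB differential-expression caller for two treatment groups:
#' median-of-ratios normalisation, per-gene method-of-moments dispersion
#' `alpha_hat = max(0, (s^2 - mean) / mean^2)` pooled across the two groups
#' (floored at `dispersion_floor`, no shrinkage across genes), and a Wald
#' test on the difference of log2 group means with a delta-method standard
#' error from the NB variance mu + alpha * mu^2. log2 fold changes carry a 0.5
#' pseudo-count (comparison over baseline); the test statistic itself does
#' not. P-values are BH-adjusted over all tested genes; genes with all-zero
#' counts in both groups are excluded and reported via
#' `attr(, "excluded_genes")`. A gene is called `up` iff padj < alpha and
#' log2fc >= lfc_min, `down` iff padj < alpha and log2fc <= -lfc_min
#' (strict `<` on padj, `>=` on the fold change), otherwise `ns`.
#'
#' @param counts Tibble (`gene` + sample columns) or a `dm_counts` object.
#' @param design Design tibble (`sample`, `treatment`, ...); ignored when
#'   `counts` is a `dm_counts`.
#' @param baseline,comparison Treatment labels; log2fc is comparison over
#'   baseline.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param lfc_min Minimum |log2 fold change| for a call (default 1).
#' @param size_factors Optional tibble from [estimate_size_factors()];
#'   computed from the two groups' samples when NULL.
#' @param dispersion_floor Lower bound on the dispersion estimate.
#' @return A `dm_contrast` tibble: gene, baseline, comparison, base_mean,
#'   log2fc, stat, pvalue, padj, call.
#' @examples
#' sim <- simulate_drought_memory(sim_config(n_genes = 200, seed = 1))
#' res <- nb_test(sim$counts, sim$design, "R0", "S1")
#' dplyr::count(res, call)
#' @export
nb_test <- function(counts, design = NULL, baseline, comparison,
                    alpha = 0.05, lfc_min = 1, size_factors = NULL,
                    dispersion_floor = 1e-8) {
  if (inherits(counts, "dm_counts")) {
    design <- counts$design
    counts <- counts$counts
  }
  if (is.null(design)) abort("a design table is required")
  assert_columns(design, c("sample", "treatment"), "design table")
  m <- counts_df_to_matrix(counts)
  sel <- design$treatment %in% c(baseline, comparison)
  samples <- design$sample[sel]
  grp <- design$treatment[sel]
  if (!all(samples %in% colnames(m))) abort("design samples missing from counts")
  m <- m[, samples, drop = FALSE]
  nA <- sum(grp == baseline); nB <- sum(grp == comparison)
  if (nA < 2 || nB < 2) {
    abort(sprintf("need >= 2 replicates per group (got %d in %s, %d in %s)",
                  nA, baseline, nB, comparison))
  }

  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$sample)]
  norm <- sweep(m, 2, sf, "/")

  A <- norm[, grp == baseline, drop = FALSE]
  B <- norm[, grp == comparison, drop = FALSE]
  tested <- rowSums(m) > 0
  excluded <- rownames(m)[!tested]

  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1, var); vB <- apply(B, 1, var)
  # pooled MoM dispersion across the two groups
  disp_of <- function(mu, s2) ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  disp <- pmax((disp_of(mA, vA) * (nA - 1) + disp_of(mB, vB) * (nB - 1)) /
                 (nA + nB - 2),
               dispersion_floor)

  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  # delta method: var(log2 mean) = (mu + alpha mu^2) / (n mu^2 ln(2)^2)
  eps <- 1e-8
  se2 <- ((mA + disp * mA^2) / (nA * pmax(mA, eps)^2) +
            (mB + disp * mB^2) / (nB * pmax(mB, eps)^2)) / log(2)^2
  stat <- (log2(pmax(mB, eps)) - log2(pmax(mA, eps))) / sqrt(se2)
  stat[mA == 0 & mB == 0] <- 0
  pvalue <- 2 * pnorm(-abs(stat))
  pvalue[!tested] <- NA_real_
  stat[!tested] <- NA_real_
  padj <- rep(NA_real_, length(pvalue))
  padj[tested] <- bh_adjust(pvalue[tested])

  res <- tibble(gene = rownames(m), baseline = baseline,
                comparison = comparison,
                base_mean = unname((mA * nA + mB * nB) / (nA + nB)),
                log2fc = unname(log2fc), stat = unname(stat),
                pvalue = unname(pvalue), padj = unname(padj),
                call = unname(call_from_thresholds(log2fc, padj, alpha,
                                                   lfc_min)))
  res$call[!tested] <- "ns"
  res <- structure(res, class = c("dm_contrast", class(res)),
                   alpha = alpha, lfc_min = lfc_min,
                   excluded_genes = excluded)
  res
}

#' Load an externally produced contrast table
#'
#' Accepts a TSV with columns `gene`, `log2fc` (or `log2FoldChange`) and
#' `padj`, e.g. DESeq2 output, and applies the package's calling rule so the
#' classifier can consume it.
#'
#' @param path TSV path.
#' @param baseline,comparison Treatment labels recorded on the result.
#' @inheritParams nb_test
#' @return A `dm_contrast` tibble.
#' @export
read_contrast <- function(path, baseline, comparison,
                          alpha = 0.05, lfc_min = 1) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("log2FoldChange" %in% names(df)) df <- rename(df, log2fc = "log2FoldChange")
  assert_columns(df, c("gene", "log2fc", "padj"), "contrast table")
  res <- tibble(gene = df$gene, baseline = baseline, comparison = comparison,
                base_mean = if ("base_mean" %in% names(df)) df$base_mean else NA_real_,
                log2fc = df$log2fc,
                stat = if ("stat" %in% names(df)) df$stat else NA_real_,
                pvalue = if ("pvalue" %in% names(df)) df$pvalue else NA_real_,
                padj = df$padj,
                call = call_from_thresholds(df$log2fc, df$padj, alpha, lfc_min))
  structure(res, class = c("dm_contrast", class(res)),
            alpha = alpha, lfc_min = lfc_min, excluded_genes = character(0))
}
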