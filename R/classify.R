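#' Trajectory category from two differential-expression calls
#'
#' Maps the (S1-vs-R0, S3-vs-S1) call pair onto the nine trajectory
#' categories: memory genes `[+/+]`, `[-/-]`, `[+/-]`, `[-/+]` (responsive in
#' S1 and changed again at S3), non-memory genes `[+/=]`, `[-/=]` (responsive
#' in S1, flat afterwards), late-response genes `[=/+]`, `[=/-]` (flat in S1,
#' responsive at S3), and `none`. `=` means "not significant at the DEG
#' thresholds", not numerically equal.
#'
#' @param s1_call,s3_call Character vectors over `{"up", "down", "ns"}`:
#'   calls for the S1-vs-R0 and S3-vs-S1 contrasts.
#' @return Character vector of category labels.
#' @examples
#' classify_gene("up", "down")   # "[+/-]"
#' classify_gene("ns", "ns")     # "none"
#' @export
classify_gene <- function(s1_call, s3_call) {
  valid <- c("up", "down", "ns")
  bad <- unique(c(s1_call, s3_call)[!c(s1_call, s3_call) %in% valid])
  if (length(bad) > 0) {
    abort(sprintf("unknown call token(s): %s", paste(bad, collapse = ", ")))
  }
  sym <- c(up = "+", down = "-", ns = "=")
  out <- paste0("[", sym[s1_call], "/", sym[s3_call], "]")
  out[s1_call == "ns" & s3_call == "ns"] <- "none"
  unname(out)
}

#' Classify every gene from the two primary contrasts
#'
#' Outer-joins the S1-vs-R0 and S3-vs-S1 contrast results on gene and assigns
#' each gene a trajectory category. Genes present in only one contrast are
#' treated as `ns` in the other (with a warning), so a gene tested only at S1
#' can still be a non-memory gene.
#'
#' @param contrast_s1 `dm_contrast` (or tibble with `gene`, `call`) for
#'   S1 vs R0.
#' @param contrast_s3 `dm_contrast` for S3 vs S1.
#' @param ecotype Ecotype label stamped on the records.
#' @param second_contrast_vs `"S1"` (default; the second symbol compares S3
#'   with S1, matching the chained inequalities R0 < S1 > S3 etc.) is the only
#'   supported interpretation baked into the contrasts the caller supplies;
#'   pass a S3-vs-R0 contrast as `contrast_s3` to use the alternative
#'   convention.
#' @return Tibble of class `dm_dmg`: gene, ecotype, s1_call, s3_call,
#'   category.
#' @export
classify_all <- function(contrast_s1, contrast_s3, ecotype = "AEX",
                         second_contrast_vs = "S1") {
  for (df in list(contrast_s1, contrast_s3)) {
    assert_columns(df, c("gene", "call"), "contrast table")
    if (anyDuplicated(df$gene)) {
      abort("duplicate gene in a contrast table")
    }
  }
  s1 <- select(as_tibble(contrast_s1), "gene", s1_call = "call")
  s3 <- select(as_tibble(contrast_s3), "gene", s3_call = "call")
  merged <- dplyr::full_join(s1, s3, by = "gene")
  n_fill <- sum(is.na(merged$s1_call)) + sum(is.na(merged$s3_call))
  if (n_fill > 0) {
    warn(sprintf("%d gene(s) present in only one contrast treated as ns in the other",
                 n_fill))
  }
  merged$s1_call[is.na(merged$s1_call)] <- "ns"
  merged$s3_call[is.na(merged$s3_call)] <- "ns"
  out <- tibble(gene = merged$gene, ecotype = ecotype,
                s1_call = merged$s1_call, s3_call = merged$s3_call,
                category = classify_gene(merged$s1_call, merged$s3_call))
  structure(out, class = c("dm_dmg", class(out)),
            second_contrast_vs = second_contrast_vs)
}

#' Category-count summary with the standard percentage bases
#'
#' Builds the drought-memory summary table from per-category gene counts.
#' Drought-responsive genes (DEGs) are those significant in S1 vs R0
#' (memory + non-memory categories); their percentage base is the total gene
#' count. Non-memory and memory totals are reported as percentages of DEGs;
#' each memory subtype as a percentage of memory genes; late-response genes
#' as a percentage of total genes. Percentages are half-up rounded to one
#' decimal.
#'
#' @param records A `dm_dmg` tibble from [classify_all()], or a named numeric
#'   vector of per-category counts over the eight non-`none` labels.
#' @param total_genes Total genes identified by RNA-seq (the percentage base
#'   for DEGs and late-response genes); must be positive.
#' @return A list of class `dm_dmg_summary`: `counts` (named vector over the
#'   eight categories), `total_genes`, and `table` — a tibble with columns
#'   group, category, count, percent, percent_base.
#' @examples
#' dmg_summary(c("[+/+]" = 115, "[-/-]" = 165, "[+/-]" = 539, "[-/+]" = 520,
#'               "[+/=]" = 1211, "[-/=]" = 1841, "[=/+]" = 606, "[=/-]" = 452),
#'             total_genes = 41458)
#' @export
dmg_summary <- function(records, total_genes) {
  assert_scalar_number(total_genes, "total_genes", lower = 1)
  cats <- setdiff(DM_CATEGORIES, "none")
  if (is.data.frame(records)) {
    assert_columns(records, "category", "DMG records")
    if (length(unique(records$gene)) > total_genes) {
      abort("total_genes is smaller than the number of distinct genes")
    }
    counts <- vapply(cats, function(cc) sum(records$category == cc),
                     numeric(1))
  } else {
    missing <- setdiff(cats, names(records))
    if (length(missing) > 0) {
      abort(sprintf("missing category count(s): %s",
                    paste(missing, collapse = ", ")))
    }
    counts <- records[cats]
  }
  deg <- sum(counts[c(MEMORY_CATEGORIES, NON_MEMORY_CATEGORIES)])
  memory <- sum(counts[MEMORY_CATEGORIES])
  non_memory <- sum(counts[NON_MEMORY_CATEGORIES])
  late <- sum(counts[LATE_CATEGORIES])
  induced <- sum(counts[c("[+/+]", "[+/-]", "[+/=]")])
  repressed <- sum(counts[c("[-/-]", "[-/+]", "[-/=]")])

  pct <- function(x, base) if (base > 0) round_half_up(x / base * 100, 1) else NA_real_
  tab <- bind_rows(
    tibble(group = "drought_response", category = "DEG", count = deg,
           percent = pct(deg, total_genes), percent_base = "total_genes"),
    tibble(group = "drought_response", category = c("induced", "repressed"),
           count = c(induced, repressed), percent = NA_real_,
           percent_base = NA_character_),
    tibble(group = "non_memory", category = "non_memory", count = non_memory,
           percent = pct(non_memory, deg), percent_base = "DEG"),
    tibble(group = "non_memory", category = NON_MEMORY_CATEGORIES,
           count = unname(counts[NON_MEMORY_CATEGORIES]), percent = NA_real_,
           percent_base = NA_character_),
    tibble(group = "memory", category = "memory", count = memory,
           percent = pct(memory, deg), percent_base = "DEG"),
    tibble(group = "memory", category = MEMORY_CATEGORIES,
           count = unname(counts[MEMORY_CATEGORIES]),
           percent = unname(vapply(counts[MEMORY_CATEGORIES], pct,
                                   numeric(1), base = memory)),
           percent_base = "memory"),
    tibble(group = "late_response", category = "late_response", count = late,
           percent = pct(late, total_genes), percent_base = "total_genes"),
    tibble(group = "late_response", category = LATE_CATEGORIES,
           count = unname(counts[LATE_CATEGORIES]), percent = NA_real_,
           percent_base = NA_character_))

  structure(list(counts = counts, total_genes = total_genes, table = tab),
            class = "dm_dmg_summary")
}

#' @export
print.dm_dmg_summary <- function(x, ...) {
  cat(sprintf("Drought-memory classification summary (%d total genes)\n",
              x$total_genes))
  print(x$table, n = nrow(x$table))
  invisible(x)
}
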