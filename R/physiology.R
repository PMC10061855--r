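#' Validate leaf-weight records
#'
#' Checks the mass-order invariants of leaf-weight records: `0 < DW`,
#' `DW <= wilted_weight`, `DW <= FW`, `FW <= TW`. Violating records are
#' rejected with a per-record report, never silently clipped.
#'
#' @param records Data frame with columns `FW`, `TW`, `wilted_weight`, `DW`
#'   (grams) and any grouping columns (typically `ecotype`, `stage`).
#' @return The records as a tibble, invisibly validated.
#' @export
validate_leaf_weights <- function(records) {
  records <- as_tibble(records)
  assert_columns(records, c("FW", "TW", "wilted_weight", "DW"),
                 "leaf-weight table")
  bad <- with(records, DW <= 0 | DW > wilted_weight | DW > FW | FW > TW)
  if (any(bad)) {
    idx <- which(bad)
    abort(paste0(
      "leaf-weight records violate mass-order invariants ",
      "(need 0 < DW <= wilted_weight, DW <= FW <= TW) at row(s): ",
      paste(head(idx, 10), collapse = ", "),
      if (length(idx) > 10) sprintf(" (and %d more)", length(idx) - 10) else ""))
  }
  records
}

#' Read leaf-weight records from TSV
#'
#' @param path TSV with columns `sample_id`, `ecotype`, `stage`, `FW`, `TW`,
#'   `wilted_weight`, `DW`.
#' @return Validated tibble of records.
#' @export
read_leaf_weights <- function(path) {
  validate_leaf_weights(readr::read_tsv(path, show_col_types = FALSE))
}

#' Leaf relative water content (%)
#'
#' RWC = (FW - DW) / (TW - DW) * 100. Falls in \[0, 100\] whenever the
#' mass-order invariants hold; increasing in FW, decreasing in TW.
#'
#' @param records Data frame of leaf-weight records (see
#'   [validate_leaf_weights()]).
#' @return The records with an `RWC` column appended (percent).
#' @examples
#' relative_water_content(
#'   data.frame(FW = 2, TW = 2.5, wilted_weight = 1.4, DW = 0.5))$RWC
#' @export
relative_water_content <- function(records) {
  records <- validate_leaf_weights(records)
  if (any(records$TW == records$DW)) {
    abort("RWC undefined: TW equals DW for some record(s)")
  }
  mutate(records, RWC = (.data$FW - .data$DW) / (.data$TW - .data$DW) * 100)
}

#' Leaf water loss of isolated leaves (g/g)
#'
#' water loss = (FW - wilted_weight) / DW; non-negative under the mass-order
#' invariants, and invariant to rescaling all masses (ratio homogeneity).
#'
#' @inheritParams relative_water_content
#' @return The records with a `water_loss` column appended (g water per g dry
#'   mass).
#' @export
water_loss <- function(records) {
  records <- validate_leaf_weights(records)
  mutate(records,
         water_loss = (.data$FW - .data$wilted_weight) / .data$DW)
}

# Compact-letter display from a pairwise "not significantly different"
# relation: insert-and-absorb over groups ordered by decreasing mean.
# `same[i, j]` is TRUE when groups i and j are indistinguishable.
compact_letters <- function(same, order) {
  k <- nrow(same)
  letter_sets <- list(order[1])
  for (g in order[-1]) {
    placed <- FALSE
    for (s in seq_along(letter_sets)) {
      if (all(same[g, letter_sets[[s]]])) {
        letter_sets[[s]] <- c(letter_sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) letter_sets[[length(letter_sets) + 1]] <- g
  }
  out <- character(k)
  for (s in seq_along(letter_sets)) {
    out[letter_sets[[s]]] <- paste0(out[letter_sets[[s]]], letters[s])
  }
  out
}

#' Summarise a water-status index by (ecotype, stage) group
#'
#' Per-group mean, SD and n; within each ecotype a one-way ANOVA across stages
#' plus pairwise Welch t-tests rendered as a compact letter display (groups
#' sharing a letter do not differ at `alpha`); between-ecotype per-stage
#' two-sample t-tests flagged `*` (p < 0.05) / `**` (p < 0.01). Pairwise
#' p-values are used raw by default, mirroring the common reporting
#' convention; set `p_adjust = "BH"` for a corrected display.
#'
#' @param records Leaf-weight records.
#' @param index `"RWC"` or `"water_loss"`.
#' @param alpha Significance level for the letter display.
#' @param p_adjust Method passed to [stats::p.adjust()] for the pairwise
#'   within-ecotype tests (`"none"` by default).
#' @return A `dm_physio_summary`: tibble with columns ecotype, stage, mean,
#'   sd, n, letters, ecotype_diff_p, flag; ANOVA p-values in
#'   `attr(, "anova")`.
#' @export
summarize_physiology <- function(records, index = c("RWC", "water_loss"),
                                 alpha = 0.05, p_adjust = "none") {
  index <- match.arg(index)
  records <- if (index == "RWC") relative_water_content(records)
             else water_loss(records)
  assert_columns(records, c("ecotype", "stage"), "leaf-weight table")
  records$stage <- as.character(records$stage)
  records$value <- records[[index]]

  groups <- records %>%
    group_by(.data$ecotype, .data$stage) %>%
    summarise(mean = mean(.data$value), sd = sd(.data$value), n = n(),
              .groups = "drop")
  if (nrow(groups) < 2) warn("fewer than two groups: no tests performed")

  anova_p <- list()
  groups$letters <- NA_character_
  for (eco in unique(groups$ecotype)) {
    sub <- filter(records, .data$ecotype == eco)
    stages <- unique(sub$stage)
    k <- length(stages)
    if (k < 2 || any(table(sub$stage) < 2)) next
    anova_p[[eco]] <-
      summary(aov(value ~ stage, data = sub))[[1]][["Pr(>F)"]][1]
    pmat <- matrix(1, k, k, dimnames = list(stages, stages))
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      pmat[i, j] <- pmat[j, i] <-
        t.test(sub$value[sub$stage == stages[i]],
               sub$value[sub$stage == stages[j]])$p.value
    }
    if (p_adjust != "none") {
      up <- upper.tri(pmat)
      pmat[up] <- p.adjust(pmat[up], method = p_adjust)
      pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
    }
    same <- pmat > alpha
    means <- vapply(stages, function(s) mean(sub$value[sub$stage == s]),
                    numeric(1))
    lets <- compact_letters(same, order(means, decreasing = TRUE))
    idx <- match(groups$stage[groups$ecotype == eco], stages)
    groups$letters[groups$ecotype == eco] <- lets[idx]
  }

  # between-ecotype per-stage tests
  groups$ecotype_diff_p <- NA_real_
  ecos <- unique(records$ecotype)
  if (length(ecos) == 2) {
    for (st in unique(groups$stage)) {
      a <- records$value[records$ecotype == ecos[1] & records$stage == st]
      b <- records$value[records$ecotype == ecos[2] & records$stage == st]
      if (length(a) >= 2 && length(b) >= 2) {
        groups$ecotype_diff_p[groups$stage == st] <- t.test(a, b)$p.value
      }
    }
  }
  groups$flag <- dplyr::case_when(
    is.na(groups$ecotype_diff_p) ~ "",
    groups$ecotype_diff_p < 0.01 ~ "**",
    groups$ecotype_diff_p < 0.05 ~ "*",
    TRUE ~ "")
  structure(groups, class = c("dm_physio_summary", class(groups)),
            anova = anova_p, index = index, alpha = alpha)
}
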