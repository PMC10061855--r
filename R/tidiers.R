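#' Tidy a differential-expression contrast
#'
#' @param x A `dm_contrast` from [nb_test()].
#' @param ... Unused.
#' @return The per-gene result tibble (gene, log2fc, pvalue, padj, call, ...).
#' @method tidy dm_contrast
#' @export
tidy.dm_contrast <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' One-row summary of a contrast
#'
#' @inheritParams tidy.dm_contrast
#' @return Tibble: n_tested, n_up, n_down, n_excluded, alpha, lfc_min.
#' @method glance dm_contrast
#' @export
glance.dm_contrast <- function(x, ...) {
  tibble(n_tested = sum(!is.na(x$padj)),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"),
         n_excluded = length(attr(x, "excluded_genes")),
         alpha = attr(x, "alpha"),
         lfc_min = attr(x, "lfc_min"))
}

#' Tidy a classification summary
#'
#' @param x A `dm_dmg_summary` from [dmg_summary()].
#' @param ... Unused.
#' @return The summary table tibble (group, category, count, percent,
#'   percent_base).
#' @method tidy dm_dmg_summary
#' @export
tidy.dm_dmg_summary <- function(x, ...) x$table

#' One-row overview of a classification summary
#'
#' @inheritParams tidy.dm_dmg_summary
#' @return Tibble: total_genes, deg, memory, non_memory, late_response.
#' @method glance dm_dmg_summary
#' @export
glance.dm_dmg_summary <- function(x, ...) {
  tab <- x$table
  pick <- function(cc) tab$count[tab$category == cc][1]
  tibble(total_genes = x$total_genes, deg = pick("DEG"),
         memory = pick("memory"), non_memory = pick("non_memory"),
         late_response = pick("late_response"))
}

#' Tidy a physiology summary
#'
#' @param x A `dm_physio_summary` from [summarize_physiology()].
#' @param ... Unused.
#' @return The group-summary tibble.
#' @method tidy dm_physio_summary
#' @export
tidy.dm_physio_summary <- function(x, ...) as_tibble(unclass_first(x))

#' One-row overview of a physiology summary
#'
#' @inheritParams tidy.dm_physio_summary
#' @return Tibble: index, alpha, n_groups and per-ecotype ANOVA p-values.
#' @method glance dm_physio_summary
#' @export
glance.dm_physio_summary <- function(x, ...) {
  an <- attr(x, "anova")
  out <- tibble(index = attr(x, "index"), alpha = attr(x, "alpha"),
                n_groups = nrow(x))
  for (eco in names(an)) out[[paste0("anova_p_", eco)]] <- an[[eco]]
  out
}

#' Tidy a switch-module table
#'
#' @param x A `dm_modules` from [detect_switch_modules()].
#' @param ... Unused.
#' @return Long tibble: module, role (positive_tf / negative_tf / member),
#'   gene.
#' @method tidy dm_modules
#' @export
tidy.dm_modules <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(module = integer(0), role = character(0),
                  gene = character(0)))
  }
  purrr::pmap_dfr(
    list(x$module, x$positive_tfs, x$negative_tfs, x$members),
    function(mod, pos, neg, mem) {
      bind_rows(tibble(module = mod, role = "positive_tf", gene = pos),
                tibble(module = mod, role = "negative_tf", gene = neg),
                tibble(module = mod, role = "member", gene = mem))
    })
}

# drop the package's S3 class tag, keeping the tibble classes
unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("dm_contrast", "dm_physio_summary",
                                  "dm_edges", "dm_modules", "dm_hubs",
                                  "dm_hierarchy", "dm_enrichment", "dm_dmg"))
  x
}
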