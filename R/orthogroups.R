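#' Read an orthogroup membership table
#'
#' Parses the OrthoFinder `Orthogroups.tsv` dialect: first column the
#' orthogroup (OG) ID, one column per species, cells holding comma-separated
#' gene IDs (possibly empty). Genes are whitespace-trimmed; a gene appearing
#' in more than one OG within the same species is an error.
#'
#' @param path TSV path.
#' @return Long tibble: `orthogroup`, `species`, `gene`.
#' @export
load_orthogroups <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (ncol(wide) < 2) abort("orthogroup table needs an OG column plus species columns")
  names(wide)[1] <- "orthogroup"
  long <- wide %>%
    tidyr::pivot_longer(-"orthogroup", names_to = "species",
                        values_to = "genes") %>%
    filter(!is.na(.data$genes), .data$genes != "") %>%
    mutate(gene = stringr::str_split(.data$genes, ",")) %>%
    select(-"genes") %>%
    tidyr::unnest("gene") %>%
    mutate(gene = stringr::str_trim(.data$gene)) %>%
    filter(.data$gene != "")
  dup <- long %>%
    distinct(.data$orthogroup, .data$species, .data$gene) %>%
    count(.data$species, .data$gene) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("gene(s) assigned to multiple orthogroups within a species: %s",
                  paste(head(paste0(dup$species, ":", dup$gene), 10),
                        collapse = ", ")))
  }
  distinct(long, .data$orthogroup, .data$species, .data$gene)
}

#' Partition orthogroups into drought-memory hierarchies
#'
#' Venn partition of the orthogroups (OGs) that contain at least one
#' drought-memory gene (DMG), over three parties: the two focal ecotypes and
#' the outgroup species collapsed into one "other plants" party. An OG
#' "contains" a party when at least one of that party's DMGs is a member
#' (mere gene presence does not count). Tiers:
#' \describe{
#'   \item{shared}{DMGs from both focal ecotypes and at least one outgroup.}
#'   \item{focal_shared}{both focal ecotypes, no outgroup DMG (the
#'     species-unique tier).}
#'   \item{ecotype_A_unique / ecotype_B_unique}{exactly one focal ecotype,
#'     no outgroup DMG.}
#'   \item{ecotype_A_with_other / ecotype_B_with_other}{one focal ecotype
#'     plus an outgroup (the pairwise Venn regions).}
#'   \item{other_only}{outgroup DMGs only.}
#' }
#' Focal DMGs absent from every OG are, by default, retained as flagged
#' singleton ecotype-unique entries (orthogroup `singleton:<gene>`) rather
#' than silently dropped.
#'
#' @param ogs Long orthogroup tibble from [load_orthogroups()].
#' @param dmg_sets Named list: species -> character vector of DMG IDs.
#' @param focal Length-2 character: the two focal species/ecotype column
#'   names (A, B).
#' @param outgroups Character vector of outgroup species column names.
#' @param include_singletons Keep non-OG focal DMGs as singleton entries.
#' @return A `dm_hierarchy` tibble: orthogroup, tier, has_A, has_B,
#'   has_other, singleton; per-gene projection in `attr(, "genes")`
#'   (tibble: gene, species, orthogroup, tier).
#' @export
partition_orthogroups <- function(ogs, dmg_sets, focal,
                                  outgroups, include_singletons = TRUE) {
  if (length(focal) != 2) abort("focal must name exactly two species")
  known <- unique(ogs$species)
  unknown <- setdiff(c(focal, outgroups), known)
  if (length(unknown) > 0) {
    abort(sprintf("species not present in the orthogroup table: %s",
                  paste(unknown, collapse = ", ")))
  }
  unknown_dmg <- setdiff(names(dmg_sets), c(focal, outgroups))
  if (length(unknown_dmg) > 0) {
    abort(sprintf("dmg_sets names unknown species: %s",
                  paste(unknown_dmg, collapse = ", ")))
  }

  is_dmg <- purrr::map2(ogs$species, ogs$gene,
                        ~ .y %in% dmg_sets[[.x]])
  hits <- ogs[unlist(is_dmg), , drop = FALSE]
  hits$party <- dplyr::case_when(
    hits$species == focal[1] ~ "A",
    hits$species == focal[2] ~ "B",
    TRUE ~ "other")

  flags <- hits %>%
    group_by(.data$orthogroup) %>%
    summarise(has_A = any(.data$party == "A"),
              has_B = any(.data$party == "B"),
              has_other = any(.data$party == "other"),
              .groups = "drop") %>%
    mutate(singleton = FALSE)

  if (include_singletons) {
    for (i in 1:2) {
      sp <- focal[i]
      in_og <- unique(ogs$gene[ogs$species == sp])
      loners <- setdiff(dmg_sets[[sp]], in_og)
      if (length(loners) > 0) {
        flags <- bind_rows(flags, tibble(
          orthogroup = paste0("singleton:", loners),
          has_A = i == 1, has_B = i == 2, has_other = FALSE,
          singleton = TRUE))
      }
    }
  }

  flags$tier <- dplyr::case_when(
    flags$has_A & flags$has_B & flags$has_other ~ "shared",
    flags$has_A & flags$has_B ~ "focal_shared",
    flags$has_A & flags$has_other ~ "ecotype_A_with_other",
    flags$has_B & flags$has_other ~ "ecotype_B_with_other",
    flags$has_A ~ "ecotype_A_unique",
    flags$has_B ~ "ecotype_B_unique",
    TRUE ~ "other_only")

  gene_proj <- hits %>%
    filter(.data$party != "other") %>%
    left_join(select(flags, "orthogroup", "tier"), by = "orthogroup") %>%
    select("gene", "species", "orthogroup", "tier")
  if (include_singletons) {
    single <- filter(flags, .data$singleton)
    if (nrow(single) > 0) {
      gene_proj <- bind_rows(gene_proj, tibble(
        gene = sub("^singleton:", "", single$orthogroup),
        species = ifelse(single$has_A, focal[1], focal[2]),
        orthogroup = single$orthogroup, tier = single$tier))
    }
  }

  out <- select(flags, "orthogroup", "tier", "has_A", "has_B", "has_other",
                "singleton")
  structure(out, class = c("dm_hierarchy", class(out)),
            genes = gene_proj, focal = focal, outgroups = outgroups)
}

#' Orthogroup counts per hierarchy tier
#'
#' @param partition A `dm_hierarchy` from [partition_orthogroups()].
#' @return Named integer vector over all seven tiers (zeros included); sums
#'   to the number of partitioned OGs.
#' @export
venn_counts <- function(partition) {
  tiers <- c("shared", "focal_shared", "ecotype_A_unique", "ecotype_B_unique",
             "ecotype_A_with_other", "ecotype_B_with_other", "other_only")
  tab <- table(factor(partition$tier, levels = tiers))
  setNames(as.integer(tab), tiers)
}

#' Genes of one focal ecotype in one hierarchy tier
#'
#' Projects the orthogroup partition back to genes, e.g. the AEX genes whose
#' OG is in the `shared` tier — the gene sets on which hierarchy-wise
#' co-expression analysis runs.
#'
#' @param partition A `dm_hierarchy`.
#' @param species Focal species/ecotype name.
#' @param tier Tier label (see [partition_orthogroups()]).
#' @return Character vector of gene IDs.
#' @export
hierarchy_genes <- function(partition, species, tier) {
  gp <- attr(partition, "genes")
  sort(unique(gp$gene[gp$species == species & gp$tier == tier]))
}
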