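#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene in a sample relative to a calibrator sample,
#' both normalised against reference-gene Ct values:
#' `2^-((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))`.
#' When several reference genes are used, pass their mean Ct (averaging Cts
#' corresponds to the geometric mean of the reference abundances, the
#' standard multi-reference rule).
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample.
#' @return Fold change (vectorised).
#' @examples
#' ddct_relative_expression(20, 18, 22, 18)  # 4-fold up
#' @export
ddct_relative_expression <- function(ct_target, ct_reference,
                                     ct_target_cal, ct_reference_cal) {
  if (any(c(ct_target, ct_reference, ct_target_cal, ct_reference_cal) <= 0)) {
    abort("Ct values must be positive")
  }
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^-ddct
}

#' Run the full drought-memory analysis on one dataset
#'
#' Orchestrates the standard stages on a simulated or loaded dataset:
#' FPKM normalisation, the two primary differential-expression contrasts
#' (S1 vs R0, S3 vs S1), trajectory classification and its summary, the
#' regulatory/functional split, signed TF co-expression and switch-module
#' detection. Orthogroup partitioning, enrichment and hub scoring run only
#' when their inputs are supplied (they need external tables that an
#' expression dataset alone does not carry).
#'
#' @param sim A `dm_sim` from [simulate_drought_memory()], or a `dm_counts`
#'   plus `gene_lengths=`/`regulators=` arguments.
#' @param gene_lengths,regulators Optional overrides; default to the
#'   simulation's own tables.
#' @param orthogroups,dmg_sets,focal,outgroups Optional orthogroup inputs for
#'   [partition_orthogroups()].
#' @param annotation Optional annotation tibble for [enrich()] of the memory
#'   genes.
#' @param network_edges Optional interaction edge list for [mcc_score()].
#' @param alpha,lfc_min DEG thresholds (defaults 0.05, 1).
#' @param r_min,p_max,min_module_size Switch thresholds (defaults 0.9, 0.05,
#'   5).
#' @return A list of class `dm_pipeline`: per-stage results (`contrast_s1`,
#'   `contrast_s3`, `dmg`, `summary`, `split`, `edges`, `modules`, optional
#'   `hierarchy`, `enrichment`, `hubs`) and a `manifest` tibble of per-stage
#'   row counts.
#' @export
run_pipeline <- function(sim, gene_lengths = NULL, regulators = NULL,
                         orthogroups = NULL, dmg_sets = NULL, focal = NULL,
                         outgroups = NULL, annotation = NULL,
                         network_edges = NULL,
                         alpha = 0.05, lfc_min = 1,
                         r_min = 0.9, p_max = 0.05, min_module_size = 5) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(p_max, "p_max", 0, 1)
  assert_scalar_number(r_min, "r_min", 0, 1)
  if (inherits(sim, "dm_sim")) {
    counts <- sim$counts
    design <- sim$design
    if (is.null(gene_lengths)) gene_lengths <- sim$gene_lengths
    if (is.null(regulators)) regulators <- sim$truth_regulators
    ecotype <- sim$config$ecotype
  } else if (inherits(sim, "dm_counts")) {
    counts <- sim$counts
    design <- sim$design
    ecotype <- design$ecotype[1]
  } else {
    abort("sim must be a dm_sim or dm_counts object")
  }
  if (is.null(gene_lengths)) abort("gene_lengths required")
  if (is.null(regulators)) regulators <- character(0)

  c1 <- nb_test(counts, design, "R0", "S1", alpha = alpha, lfc_min = lfc_min)
  c3 <- nb_test(counts, design, "S1", "S3", alpha = alpha, lfc_min = lfc_min)
  dmg <- classify_all(c1, c3, ecotype = ecotype)
  summ <- dmg_summary(dmg, total_genes = nrow(counts))

  memory_genes <- dmg$gene[dmg$category %in% MEMORY_CATEGORIES]
  split <- split_regulatory(memory_genes, regulators)
  expr <- log_fpkm_matrix(counts, gene_lengths)
  edges <- filter_edges(
    correlate(expr, split$regulatory, split$functional),
    r_min = r_min, p_max = p_max)
  modules <- detect_switch_modules(edges, min_module_size = min_module_size)

  out <- list(contrast_s1 = c1, contrast_s3 = c3, dmg = dmg, summary = summ,
              split = split, edges = edges, modules = modules)

  if (!is.null(orthogroups)) {
    if (is.null(dmg_sets) || is.null(focal) || is.null(outgroups)) {
      abort("orthogroup partitioning needs dmg_sets, focal and outgroups")
    }
    out$hierarchy <- partition_orthogroups(orthogroups, dmg_sets, focal,
                                           outgroups)
  }
  if (!is.null(annotation)) {
    out$enrichment <- enrich(memory_genes, annotation,
                             background = counts$gene, alpha = alpha)
  }
  if (!is.null(network_edges)) {
    out$hubs <- mcc_score(network_edges)
  }

  out$manifest <- tibble(
    stage = c("genes", "deg_s1", "dmg_memory", "regulatory", "functional",
              "edges", "modules",
              if (!is.null(out$hierarchy)) "orthogroups",
              if (!is.null(out$enrichment)) "enriched_terms",
              if (!is.null(out$hubs)) "network_nodes"),
    n = c(nrow(counts), sum(c1$call != "ns"), length(memory_genes),
          length(split$regulatory), length(split$functional),
          nrow(edges), nrow(modules),
          if (!is.null(out$hierarchy)) nrow(out$hierarchy),
          if (!is.null(out$enrichment)) nrow(out$enrichment),
          if (!is.null(out$hubs)) nrow(out$hubs)))
  structure(out, class = "dm_pipeline")
}

#' @export
print.dm_pipeline <- function(x, ...) {
  cat("Drought-memory pipeline run\n")
  print(x$manifest, n = nrow(x$manifest))
  invisible(x)
}
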