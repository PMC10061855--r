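#' Configure a synthetic recurring-drought experiment
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' generator emulates a control / first-dehydration / third-dehydration
#' (R0/S1/S3) bulk RNA-seq design on one ecotype: negative-binomial counts
#' with category-specific expression trajectories, a set of planted regulator
#' (TF) genes, "molecular switch" co-expression modules in which one TF tracks
#' and another mirrors a shared latent trajectory, and leaf-weight records for
#' the water-status indices.
#'
#' Default category proportions mirror a typical recurring-drought
#' transcriptome: ~4% memory genes (1% per sign pattern), ~8% non-memory
#' drought-responsive genes, ~3% late-response genes, the remainder unchanged.
#'
#' @param n_genes Number of genes to simulate.
#' @param category_proportions Named numeric over the nine trajectory labels
#'   (`"[+/+]"`, `"[-/-]"`, `"[+/-]"`, `"[-/+]"`, `"[+/=]"`, `"[-/=]"`,
#'   `"[=/+]"`, `"[=/-]"`, `"none"`); must sum to 1.
#' @param base_mean_log2_range Length-2 numeric: bounds (log2 scale) of the
#'   per-gene baseline mean expression, drawn log-uniformly.
#' @param effect_log2fc Magnitude (log2) of every planted expression shift.
#'   Values >= 1 keep planted shifts above the usual DEG fold-change threshold.
#' @param dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2), shared across genes.
#' @param n_replicates Biological replicates per treatment (>= 2).
#' @param size_factor_range Length-2 numeric: per-sample library size factors
#'   are drawn uniformly from this interval. The default `c(1, 1)` plants equal
#'   library sizes so classification error is not confounded with
#'   normalisation error.
#' @param n_tfs Number of genes flagged as regulators (TF/TR).
#' @param n_switch_modules Number of planted switch modules; each consumes one
#'   positive and one negative regulator from the TF pool.
#' @param module_size_range Length-2 integer: member-gene count per module.
#' @param noise_sd Log2-scale standard deviation of the per-gene jitter added
#'   to switch-module profiles (0 gives exactly collinear profiles).
#' @param latent_jitter_sd Log2-scale standard deviation of the shared
#'   per-sample variation of each module's latent trajectory (coherent
#'   regulator drive beyond the treatment means). Shared jitter decorrelates
#'   module profiles from genes that merely share the same treatment pattern
#'   without breaking within-module collinearity.
#' @param ecotype Ecotype label stamped on samples (`"AEX"` or `"WW"`).
#' @param n_physio Leaf-weight records per (ecotype, stage) group.
#' @param seed Integer seed; fixed seed gives a bit-identical dataset.
#'
#' @return A list of class `dm_config`.
#' @seealso [simulate_drought_memory()]
#' @export
sim_config <- function(n_genes = 2000,
                       category_proportions = c(
                         "[+/+]" = 0.01, "[-/-]" = 0.01,
                         "[+/-]" = 0.01, "[-/+]" = 0.01,
                         "[+/=]" = 0.04, "[-/=]" = 0.04,
                         "[=/+]" = 0.015, "[=/-]" = 0.015,
                         "none" = 0.85),
                       base_mean_log2_range = c(3, 10),
                       effect_log2fc = 2,
                       dispersion = 0.05,
                       n_replicates = 2,
                       size_factor_range = c(1, 1),
                       n_tfs = 6,
                       n_switch_modules = 2,
                       module_size_range = c(5, 10),
                       noise_sd = 0.05,
                       latent_jitter_sd = 0.3,
                       ecotype = "AEX",
                       n_physio = 10,
                       seed = NULL) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  missing_cat <- setdiff(DM_CATEGORIES, names(category_proportions))
  if (length(missing_cat) > 0) {
    abort(sprintf("category_proportions is missing label(s): %s",
                  paste(missing_cat, collapse = ", ")))
  }
  category_proportions <- category_proportions[DM_CATEGORIES]
  if (any(category_proportions < 0) ||
      abs(sum(category_proportions) - 1) > 1e-9) {
    abort("category_proportions must be non-negative and sum to 1")
  }
  assert_scalar_number(effect_log2fc, "effect_log2fc", lower = 0)
  assert_scalar_number(dispersion, "dispersion", lower = 1e-12)
  assert_scalar_number(n_replicates, "n_replicates", lower = 2)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(latent_jitter_sd, "latent_jitter_sd", lower = 0)
  assert_scalar_number(n_switch_modules, "n_switch_modules", lower = 0)
  assert_scalar_number(n_tfs, "n_tfs", lower = 0)
  if (n_tfs < 2 * n_switch_modules) {
    abort("n_tfs must be at least 2 * n_switch_modules (one positive and one negative regulator per module)")
  }
  if (length(base_mean_log2_range) != 2 || diff(base_mean_log2_range) < 0) {
    abort("base_mean_log2_range must be an increasing pair")
  }
  if (length(module_size_range) != 2 || diff(module_size_range) < 0 ||
      module_size_range[1] < 1) {
    abort("module_size_range must be a positive increasing pair")
  }
  if (n_switch_modules * module_size_range[2] + n_tfs > n_genes) {
    abort("module_size_range and n_tfs exceed the number of available genes")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    category_proportions = category_proportions,
    base_mean_log2_range = base_mean_log2_range,
    effect_log2fc = effect_log2fc,
    dispersion = dispersion,
    n_replicates = as.integer(n_replicates),
    size_factor_range = size_factor_range,
    n_tfs = as.integer(n_tfs),
    n_switch_modules = as.integer(n_switch_modules),
    module_size_range = as.integer(module_size_range),
    noise_sd = noise_sd,
    latent_jitter_sd = latent_jitter_sd,
    ecotype = ecotype,
    n_physio = as.integer(n_physio),
    seed = seed
  ), class = "dm_config")
}

with_config_seed <- function(config, offset, code) {
  if (is.null(config$seed)) return(code)
  withr::with_seed(as.integer(config$seed) + offset, code)
}

# per-step multiplier implied by a trajectory symbol
step_multiplier <- function(symbol, effect_log2fc) {
  switch(symbol, "+" = 2^effect_log2fc, "-" = 2^-effect_log2fc, "=" = 1,
         abort(sprintf("unknown trajectory symbol '%s'", symbol)))
}

category_symbols <- function(category) {
  if (category == "none") return(c("=", "="))
  m <- regmatches(category, regexec("^\\[([+=-])/([+=-])\\]$", category))[[1]]
  if (length(m) != 3) abort(sprintf("unknown category label '%s'", category))
  m[2:3]
}

# Treatment-level mean multipliers (R0, S1, S3) for one category; the second
# symbol chains off S1, matching the table convention "R0 < S1 > S3" etc.
category_multipliers <- function(category, effect_log2fc) {
  sym <- category_symbols(category)
  s1 <- step_multiplier(sym[1], effect_log2fc)
  s3 <- s1 * step_multiplier(sym[2], effect_log2fc)
  c(R0 = 1, S1 = s1, S3 = s3)
}

# deterministic largest-remainder allocation of n items to proportions
allocate_counts <- function(n, proportions) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate negative-binomial counts with planted trajectory categories
#'
#' Draws a gene-by-sample count matrix for one ecotype across R0/S1/S3. Each
#' gene is assigned one of the nine trajectory categories (allocation follows
#' `category_proportions` deterministically by largest remainder); its
#' treatment means follow the category's chained fold changes (e.g. `[+/-]`
#' has mean(S1) = mean(R0) * 2^effect_log2fc and mean(S3) back at mean(R0)).
#' Counts are NB with variance mu + alpha * mu^2.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `dm_sim` with elements `counts` (tibble: `gene` +
#'   one column per sample), `design` (tibble: sample, ecotype, treatment,
#'   replicate), `gene_lengths` (tibble: gene, length_bp), `truth` (tibble:
#'   gene, category, is_regulator, module), `truth_regulators`,
#'   `truth_modules` (tibble with list-columns), `physiology` (empty until
#'   [generate_physiology()] fills it), and `config`.
#' @seealso [generate_switch_profiles()], [simulate_drought_memory()]
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "dm_config"))
  with_config_seed(config, 0L, {
    n <- config$n_genes
    genes <- sprintf("g%05d", seq_len(n))
    cats <- rep(DM_CATEGORIES, allocate_counts(n, config$category_proportions))
    cats <- sample(cats)

    reps <- config$n_replicates
    design <- tidyr::expand_grid(treatment = TREATMENTS,
                                 replicate = seq_len(reps)) %>%
      mutate(ecotype = config$ecotype,
             sample = sprintf("%s_%s_%d", .data$ecotype, .data$treatment,
                              .data$replicate)) %>%
      select("sample", "ecotype", "treatment", "replicate")

    sf <- if (diff(config$size_factor_range) == 0) {
      rep(config$size_factor_range[1], nrow(design))
    } else {
      runif(nrow(design), config$size_factor_range[1],
            config$size_factor_range[2])
    }

    mu0 <- 2^runif(n, config$base_mean_log2_range[1],
                   config$base_mean_log2_range[2])
    mult <- t(vapply(cats, category_multipliers, numeric(3),
                     effect_log2fc = config$effect_log2fc))

    m <- matrix(0L, nrow = n, ncol = nrow(design),
                dimnames = list(genes, design$sample))
    for (j in seq_len(nrow(design))) {
      mu <- mu0 * mult[, design$treatment[j]] * sf[j]
      m[, j] <- rnbinom(n, mu = mu, size = 1 / config$dispersion)
    }

    structure(list(
      counts = matrix_to_counts_df(m),
      design = design,
      gene_lengths = tibble(gene = genes,
                            length_bp = as.integer(round(runif(n, 200, 5000)))),
      truth = tibble(gene = genes, category = cats,
                     is_regulator = FALSE, module = NA_integer_),
      truth_regulators = character(0),
      truth_modules = tibble(module = integer(0), category = character(0),
                             positive_tfs = list(), negative_tfs = list(),
                             members = list()),
      physiology = NULL,
      config = config
    ), class = "dm_sim")
  })
}

#' Plant regulator genes and switch-module co-expression structure
#'
#' Overwrites the count rows of the chosen module members and regulators with
#' profiles built from a shared per-module latent trajectory `z` (log2 scale):
#' members and positive regulators follow `z` plus independent `noise_sd`
#' jitter, negative regulators follow the reflection of `z` about its midrange
#' (a monotone-decreasing transform, so values stay positive and
#' Pearson-valid). At `noise_sd = 0` every profile is exactly (anti)collinear
#' with the latent on the log2 scale. Module members and their regulators are
#' assigned the module's memory trajectory category, so downstream
#' classification and switch detection can both be checked against truth.
#'
#' @param config A [sim_config()] object.
#' @param dataset A `dm_sim` from [generate_counts()].
#' @return The dataset with counts, truth, `truth_regulators` and
#'   `truth_modules` updated.
#' @export
generate_switch_profiles <- function(config, dataset) {
  stopifnot(inherits(config, "dm_config"), inherits(dataset, "dm_sim"))
  if (config$n_tfs == 0) return(dataset)
  if (config$n_switch_modules * config$module_size_range[2] + config$n_tfs >
      config$n_genes) {
    abort("module_size_range exceeds the number of available genes")
  }
  with_config_seed(config, 1L, {
    m <- counts_df_to_matrix(dataset$counts)
    truth <- dataset$truth
    genes <- truth$gene
    n_samples <- ncol(m)
    treatment <- dataset$design$treatment[match(colnames(m),
                                                dataset$design$sample)]

    tf_ids <- sample(genes, config$n_tfs)
    truth$is_regulator <- truth$gene %in% tf_ids

    modules <- list()
    used <- tf_ids
    free_tfs <- tf_ids
    n_mod <- config$n_switch_modules
    if (n_mod > 0) {
      # Module trajectory categories alternate between [+/-] and [+/+]: their
      # centred treatment patterns are orthogonal and not mirror images, so
      # distinct modules stay decorrelated. With > 2 modules categories
      # repeat and cross-module correlations rise (documented limitation).
      module_cats <- rep(c("[+/-]", "[+/+]"), length.out = n_mod)
      for (k in seq_len(n_mod)) {
        cat_k <- module_cats[k]
        size_k <- if (diff(config$module_size_range) == 0) {
          config$module_size_range[1]
        } else {
          sample(seq(config$module_size_range[1],
                     config$module_size_range[2]), 1)
        }
        pool <- setdiff(genes, used)
        members <- sample(pool, size_k)
        pos_tf <- free_tfs[1]
        neg_tf <- free_tfs[2]
        free_tfs <- free_tfs[-(1:2)]
        used <- c(used, members)

        # Shared latent trajectory on the log2 scale: category fold-pattern
        # plus shared per-sample jitter (the coherent regulator drive). In
        # the noiseless diagnostic mode the latent is rounded to integers so
        # planted counts are exact powers of two and within-module
        # correlations are exactly +/-1 even after integer rounding.
        lvl <- log2(category_multipliers(cat_k, config$effect_log2fc))
        z <- lvl[treatment] + rnorm(n_samples, 0, config$latent_jitter_sd)
        if (config$noise_sd == 0) z <- round(z)
        z_neg <- (max(z) + min(z)) - z

        plant <- function(gene, latent) {
          a <- sample(4:9, 1)
          x <- a + latent
          if (config$noise_sd > 0) x <- x + rnorm(n_samples, 0, config$noise_sd)
          m[gene, ] <<- round(2^x)
        }
        for (g in members) plant(g, z)
        plant(pos_tf, z)
        plant(neg_tf, z_neg)

        # the negative TF follows the mirrored trajectory, so its own
        # category is the reflection of the module's
        mirror <- c("[+/+]" = "[-/-]", "[-/-]" = "[+/+]",
                    "[+/-]" = "[-/+]", "[-/+]" = "[+/-]")
        truth$category[truth$gene %in% c(members, pos_tf)] <- cat_k
        truth$category[truth$gene == neg_tf] <- mirror[[cat_k]]
        truth$module[truth$gene %in% c(members, pos_tf, neg_tf)] <- k
        modules[[k]] <- tibble(module = k, category = cat_k,
                               positive_tfs = list(pos_tf),
                               negative_tfs = list(neg_tf),
                               members = list(sort(members)))
      }
    }

    dataset$counts <- matrix_to_counts_df(m)
    dataset$truth <- truth
    dataset$truth_regulators <- sort(tf_ids)
    dataset$truth_modules <- if (length(modules) > 0) {
      bind_rows(modules)
    } else {
      dataset$truth_modules
    }
    dataset
  })
}

#' Generate leaf-weight records for the water-status indices
#'
#' Emulates the six-stage dehydration/rehydration design (R0, S1, R1, S2, R2,
#' S3) for both ecotypes: fresh, turgid, wilted and dry weight per leaf, with
#' a planted drought effect (relative water content drops at every stress
#' stage, most at S1) and a planted memory contrast (the arid-land ecotype WW
#' holds its water status after the first stress; AEX recovers less).
#' Records always satisfy DW < wilted <= FW <= TW.
#'
#' @param config A [sim_config()] object (`n_physio` records per group).
#' @return Tibble: sample_id, ecotype, stage, FW, TW, wilted_weight, DW (g).
#' @export
generate_physiology <- function(config) {
  stopifnot(inherits(config, "dm_config"))
  stages <- c("R0", "S1", "R1", "S2", "R2", "S3")
  # target relative water content (%) per (ecotype, stage)
  rwc_target <- list(
    AEX = c(R0 = 95, S1 = 66, R1 = 90, S2 = 74, R2 = 84, S3 = 72),
    WW  = c(R0 = 95, S1 = 62, R1 = 91, S2 = 90, R2 = 89, S3 = 88))
  # target water loss of isolated leaves (g/g), highest at the first stress
  loss_target <- c(R0 = 1.0, S1 = 1.25, R1 = 1.0, S2 = 0.95, R2 = 0.95,
                   S3 = 0.85)
  with_config_seed(config, 2L, {
    grid <- tidyr::expand_grid(ecotype = c("AEX", "WW"), stage = stages,
                               rep = seq_len(config$n_physio))
    n <- nrow(grid)
    DW <- rnorm(n, 0.5, 0.03)
    TW <- DW * (1 + runif(n, 3.0, 3.6))
    rwc <- purrr::map2_dbl(grid$ecotype, grid$stage,
                           ~ rwc_target[[.x]][[.y]]) / 100 +
      rnorm(n, 0, 0.02)
    rwc <- pmin(pmax(rwc, 0.05), 1)
    FW <- DW + rwc * (TW - DW)
    loss <- loss_target[grid$stage] * exp(rnorm(n, 0, 0.05))
    wilted <- pmax(FW - loss * DW, DW * 1.05)
    wilted <- pmin(wilted, FW)
    tibble(sample_id = sprintf("%s_%s_%02d", grid$ecotype, grid$stage,
                               grid$rep),
           ecotype = grid$ecotype,
           stage = factor(grid$stage, levels = stages),
           FW = FW, TW = TW, wilted_weight = wilted, DW = DW)
  })
}

#' Simulate a complete drought-memory dataset
#'
#' Runs [generate_counts()], [generate_switch_profiles()] and
#' [generate_physiology()] under one configuration; the one place to get a
#' fully populated synthetic dataset with planted ground truth.
#'
#' @param config A [sim_config()] object.
#' @return A `dm_sim` list (see [generate_counts()]) with `physiology` filled.
#' @examples
#' sim <- simulate_drought_memory(sim_config(n_genes = 300, seed = 1))
#' dplyr::count(sim$truth, category)
#' @export
simulate_drought_memory <- function(config = sim_config()) {
  sim <- generate_counts(config)
  sim <- generate_switch_profiles(config, sim)
  sim$physiology <- generate_physiology(config)
  sim
}

#' Write a simulated dataset to plain-text files
#'
#' Counts, design, gene lengths and physiology as TSV; planted truth
#' (categories, regulators, modules) as JSON.
#'
#' @param sim A `dm_sim` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "dm_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$design, file.path(dir, "design.tsv"))
  readr::write_tsv(sim$gene_lengths, file.path(dir, "gene_lengths.tsv"))
  if (!is.null(sim$physiology)) {
    readr::write_tsv(sim$physiology, file.path(dir, "physiology.tsv"))
  }
  truth <- list(
    categories = setNames(as.list(sim$truth$category), sim$truth$gene),
    regulators = sim$truth_regulators,
    modules = purrr::pmap(sim$truth_modules,
                          function(module, category, positive_tfs,
                                   negative_tfs, members) {
                            list(module = module, category = category,
                                 positive_tfs = positive_tfs,
                                 negative_tfs = negative_tfs,
                                 members = members)
                          }))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
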