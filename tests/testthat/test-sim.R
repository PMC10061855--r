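test_that("fixed seed gives a bit-identical dataset", {
  cfg <- sim_config(n_genes = 300, n_replicates = 3, seed = 7)
  a <- simulate_drought_memory(cfg)
  b <- simulate_drought_memory(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$truth_modules, b$truth_modules)
  expect_identical(a$physiology, b$physiology)
})

test_that("degenerate and invalid configurations are handled", {
  sim <- generate_counts(sim_config(n_genes = 50, n_tfs = 0,
                                    n_switch_modules = 0,
                                    category_proportions = none_only_props,
                                    seed = 1))
  expect_true(all(sim$truth$category == "none"))

  bad <- none_only_props
  bad["none"] <- 0.9
  expect_error(sim_config(category_proportions = bad), "sum to 1")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(n_genes = 20, n_switch_modules = 2, n_tfs = 4,
                          module_size_range = c(10, 12)),
               "exceed")
})

test_that("planted trajectories have the advertised treatment means", {
  cfg <- sim_config(n_genes = 2000, effect_log2fc = 2, dispersion = 0.05,
                    n_replicates = 3, n_switch_modules = 0, n_tfs = 0,
                    seed = 7)
  sim <- generate_counts(cfg)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$gene
  trt <- sim$design$treatment
  for (cc in c("[+/+]", "[+/-]")) {
    genes <- sim$truth$gene[sim$truth$category == cc]
    r0 <- rowMeans(m[genes, trt == "R0", drop = FALSE])
    s1 <- rowMeans(m[genes, trt == "S1", drop = FALSE])
    # planted S1 mean is 4x the R0 mean (effect_log2fc = 2)
    expect_equal(mean(s1) / mean(r0), 4, tolerance = 0.15)
  }
  none <- sim$truth$gene[sim$truth$category == "none"]
  r0 <- rowMeans(m[none, trt == "R0", drop = FALSE])
  s1 <- rowMeans(m[none, trt == "S1", drop = FALSE])
  expect_equal(mean(s1) / mean(r0), 1, tolerance = 0.1)
})

test_that("replicate counts have negative-binomial mean-variance structure", {
  cfg <- sim_config(n_genes = 3000, dispersion = 0.05, n_replicates = 3,
                    n_switch_modules = 0, n_tfs = 0,
                    category_proportions = none_only_props, seed = 3)
  sim <- generate_counts(cfg)
  m <- as.matrix(sim$counts[-1])
  trt <- sim$design$treatment
  # pooled method-of-moments dispersion across treatments should recover
  # alpha = 0.05 within Monte-Carlo error
  alphas <- unlist(lapply(unique(trt), function(g) {
    mu <- rowMeans(m[, trt == g, drop = FALSE])
    v <- apply(m[, trt == g, drop = FALSE], 1, var)
    ((v - mu) / mu^2)[mu > 50]
  }))
  expect_lt(abs(mean(alphas) - 0.05), 0.015)
})

test_that("noiseless switch profiles are exactly (anti)collinear", {
  cfg <- sim_config(n_genes = 200, noise_sd = 0, n_switch_modules = 1,
                    n_tfs = 2, seed = 5)
  sim <- simulate_drought_memory(cfg)
  tm <- sim$truth_modules
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$gene
  pos <- tm$positive_tfs[[1]]
  neg <- tm$negative_tfs[[1]]
  for (g in tm$members[[1]]) {
    expect_equal(cor(log2(m[g, ]), log2(m[pos, ])), 1, tolerance = 1e-12)
    expect_equal(cor(log2(m[g, ]), log2(m[neg, ])), -1, tolerance = 1e-12)
  }
})

test_that("switch-module truth respects its invariants", {
  sim <- simulate_drought_memory(sim_config(n_genes = 400, seed = 2))
  expect_true(all(sim$truth_regulators %in% sim$counts$gene))
  members <- unlist(sim$truth_modules$members)
  cats <- sim$truth$category[match(members, sim$truth$gene)]
  expect_true(all(cats != "none"))

  none_mod <- simulate_drought_memory(
    sim_config(n_genes = 100, n_switch_modules = 0, n_tfs = 2, seed = 2))
  expect_identical(nrow(none_mod$truth_modules), 0L)
})

test_that("physiology records obey mass ordering and planted drought effect", {
  cfg <- sim_config(seed = 9)
  ph <- generate_physiology(cfg)
  expect_true(all(ph$DW < ph$wilted_weight))
  expect_true(all(ph$wilted_weight <= ph$FW))
  expect_true(all(ph$FW <= ph$TW))
  expect_identical(ph, generate_physiology(cfg))
  rwc <- relative_water_content(ph)
  means <- tapply(rwc$RWC, list(rwc$ecotype, as.character(rwc$stage)), mean)
  expect_true(all(means[, "R0"] > means[, "S1"]))
})

test_that("a simulated dataset round-trips through its text files", {
  dir <- withr::local_tempdir()
  sim <- simulate_drought_memory(sim_config(n_genes = 80, seed = 4))
  write_simulation(sim, dir)
  back <- read_counts(file.path(dir, "counts.tsv"),
                      file.path(dir, "design.tsv"))
  expect_equal(as.data.frame(back$counts), as.data.frame(sim$counts))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(sort(unlist(truth$regulators)), sim$truth_regulators)
})
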