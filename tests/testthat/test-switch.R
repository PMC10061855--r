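test_that("regulatory/functional split partitions the DMG set", {
  expect_identical(split_regulatory(c("a", "b", "c"), "b"),
                   list(regulatory = "b", functional = c("a", "c")))
  expect_identical(split_regulatory(c("a", "b"), character(0)),
                   list(regulatory = character(0), functional = c("a", "b")))
  expect_warning(split_regulatory(c("a", "b"), c("a", "b", "z")),
                 "not in the DMG set")
  res <- suppressWarnings(split_regulatory(c("a", "b"), c("a", "b", "z")))
  expect_identical(res$functional, character(0))
})

test_that("correlation recovers collinear and reflected profiles", {
  x <- c(1, 3, 2, 6, 4, 8)
  expr <- rbind(tf = x, same = 2 * x + 1, anti = mean(x) * 2 - x,
                flat = rep(5, 6))
  expect_warning(edges <- correlate(expr, "tf", c("same", "anti", "flat")),
                 "constant")
  expect_equal(edges$r[edges$target == "same"], 1)
  expect_equal(edges$r[edges$target == "anti"], -1)
  expect_lt(edges$pvalue[edges$target == "same"], 1e-10)
  expect_false("flat" %in% edges$target)
  expect_error(correlate(expr[, 1:2], "tf", "same"), ">= 3 samples")
})

test_that("t-based p-values match the exhaustive 720-permutation oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  profiles <- list(c(1.1, 2.3, 2.6, 4.5, 4.9, 6.2),
                   c(2, 1, 4, 3, 6, 5),
                   c(1, 3, 2, 5, 4, 6))
  for (y in profiles) {
    expr <- rbind(tf = x, tg = y)
    edge <- correlate(expr, "tf", "tg")
    perms <- all_perms(y)
    r_perm <- vapply(perms, function(p) cor(x, p), numeric(1))
    p_perm <- mean(abs(r_perm) >= abs(edge$r) - 1e-12)
    expect_lt(abs(edge$pvalue - p_perm), 0.03)
  }
})

test_that("edge filtering applies both strict thresholds and keeps signs", {
  edges <- tibble::tibble(tf = "A", target = c("t1", "t2", "t3", "t4"),
                          r = c(0.95, 0.95, -0.95, 0.85),
                          pvalue = c(0.01, 0.06, 0.01, 0.01),
                          sign = c("+", "+", "-", "+"))
  kept <- filter_edges(edges)
  expect_setequal(kept$target, c("t1", "t3"))
  expect_identical(kept$sign[kept$target == "t3"], "-")
  # boundary values are excluded (strict inequalities)
  expect_equal(nrow(filter_edges(
    tibble::tibble(tf = "A", target = "t", r = 0.9, pvalue = 0.01,
                   sign = "+"))), 0)
})

test_that("signature grouping reproduces the on-off module pattern", {
  targets <- sprintf("t%02d", 1:29)
  edges <- dplyr::bind_rows(
    tibble::tibble(tf = "A", target = targets, r = 0.95, pvalue = 1e-4,
                   sign = "+"),
    tibble::tibble(tf = "B", target = targets, r = -0.95, pvalue = 1e-4,
                   sign = "-"),
    # targets tied to a single TF: no opposing sign, no module
    tibble::tibble(tf = "A", target = sprintf("x%d", 1:8), r = 0.95,
                   pvalue = 1e-4, sign = "+"))
  mods <- detect_switch_modules(edges)
  expect_equal(nrow(mods), 1)
  expect_identical(mods$positive_tfs[[1]], "A")
  expect_identical(mods$negative_tfs[[1]], "B")
  expect_identical(mods$members[[1]], sort(targets))
  expect_equal(mods$n_members, 29)
})

test_that("module grouping matches the brute-force signature oracle", {
  set.seed(3)
  for (rep in 1:10) {
    tfs <- LETTERS[1:4]
    targets <- sprintf("t%02d", 1:40)
    edges <- tidyr::expand_grid(tf = tfs, target = targets) %>%
      dplyr::slice_sample(prop = 0.4) %>%
      dplyr::mutate(r = sample(c(0.95, -0.95), dplyr::n(), replace = TRUE),
                    pvalue = 1e-3, sign = ifelse(r > 0, "+", "-"))
    mods <- detect_switch_modules(edges, min_module_size = 2)
    oracle <- brute_modules(as.data.frame(edges), min_size = 2)
    got <- lapply(mods$members, identity)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
  }
})

test_that("grouping is order-invariant and shrinks with stricter thresholds", {
  set.seed(4)
  edges <- tidyr::expand_grid(tf = LETTERS[1:3],
                              target = sprintf("t%d", 1:30)) %>%
    dplyr::mutate(r = runif(dplyr::n(), -1, 1),
                  pvalue = runif(dplyr::n(), 0, 0.1),
                  sign = ifelse(r > 0, "+", "-"))
  f1 <- filter_edges(edges, 0.5, 0.05)
  f2 <- filter_edges(edges, 0.8, 0.05)
  expect_true(nrow(f2) <= nrow(f1))
  m1 <- detect_switch_modules(f1, min_module_size = 1)
  m_shuffled <- detect_switch_modules(f1[sample(nrow(f1)), ],
                                      min_module_size = 1)
  expect_equal(as.data.frame(m1), as.data.frame(m_shuffled))
  expect_true(nrow(detect_switch_modules(f1, min_module_size = 3)) <=
                nrow(m1))
})

test_that("planted switch modules are recovered exactly from the simulation", {
  cfg <- sim_config(n_genes = 400, n_replicates = 3, n_tfs = 2,
                    n_switch_modules = 1, module_size_range = c(5, 5),
                    noise_sd = 0.05, category_proportions = none_only_props,
                    seed = 3)
  sim <- simulate_drought_memory(cfg)
  res <- suppressWarnings(run_pipeline(sim))
  tm <- sim$truth_modules
  expect_equal(nrow(res$modules), 1)
  expect_identical(res$modules$members[[1]], tm$members[[1]])
  expect_identical(res$modules$positive_tfs[[1]], tm$positive_tfs[[1]])
  expect_identical(res$modules$negative_tfs[[1]], tm$negative_tfs[[1]])
})
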