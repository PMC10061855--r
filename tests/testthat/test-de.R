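test_that("size factors reproduce brute-force median-of-ratios on a toy", {
  A <- c(10, 20, 40, 80, 100)
  toy <- toy_two_group(cbind(A, A), cbind(2 * A, 2 * A))
  sf <- estimate_size_factors(toy$counts)
  # identical columns get identical factors
  expect_equal(sf$size_factor[1], sf$size_factor[2])
  # doubled sample has twice the factor
  expect_equal(sf$size_factor[3] / sf$size_factor[1], 2, tolerance = 1e-12)

  # independent brute-force oracle on the same matrix
  m <- cbind(A, A, 2 * A, 2 * A)
  ref <- exp(rowMeans(log(m)))
  oracle <- apply(m, 2, function(col) median(col / ref))
  expect_equal(sf$size_factor, unname(oracle))
})

test_that("degenerate count matrices fall back or fail", {
  toy <- toy_two_group(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_error(estimate_size_factors(toy$counts), "all-zero")

  # no gene expressed in every sample -> library-size fallback
  toy2 <- toy_two_group(matrix(c(5, 0), 2, 2), matrix(c(0, 10), 2, 2))
  expect_warning(sf <- estimate_size_factors(toy2$counts), "library-size")
  expect_true(all(sf$size_factor > 0))
})

test_that("BH adjustment equals the definitional step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), stepup_bh(p))
  }
})

test_that("null genes are not called and all-zero genes are excluded", {
  set.seed(1)
  base <- matrix(rnbinom(40, mu = 50, size = 20), 4, 10)
  counts <- rbind(base[, 1:5], base[, 1:5])  # identical groups, 8 genes
  toy <- toy_two_group(counts[, 1:5], counts[, 1:5])
  zero <- toy$counts[1, ]
  zero$gene <- "gzero"
  zero[-1] <- 0L
  toy$counts <- dplyr::bind_rows(toy$counts, zero)
  res <- nb_test(toy$counts, toy$design, "R0", "S1")
  expect_true(all(res$log2fc[res$gene != "gzero"] == 0))
  expect_true(all(res$call == "ns"))
  expect_identical(attr(res, "excluded_genes"), "gzero")
  expect_true(is.na(res$padj[res$gene == "gzero"]))
})

test_that("a planted 4-fold gene is called up and the call flips with the contrast", {
  set.seed(2)
  n_null <- 50
  A <- matrix(rnbinom(5 * n_null, mu = 100, size = 50), n_null, 5)
  B <- matrix(rnbinom(5 * n_null, mu = 100, size = 50), n_null, 5)
  A <- rbind(A, rnbinom(5, mu = 100, size = 50))
  B <- rbind(B, rnbinom(5, mu = 400, size = 50))
  toy <- toy_two_group(A, B)
  res <- nb_test(toy$counts, toy$design, "R0", "S1")
  planted <- res[res$gene == sprintf("g%02d", n_null + 1), ]
  expect_identical(planted$call, "up")
  expect_equal(planted$log2fc, 2, tolerance = 0.5)

  rev <- nb_test(toy$counts, toy$design, "S1", "R0")
  expect_equal(rev$log2fc, -res$log2fc)
  expect_true(all(rev$call[res$call == "up"] == "down"))
  expect_true(all(rev$call[res$call == "down"] == "up"))
  expect_identical(rev$call[rev$gene == planted$gene], "down")
})

test_that("replicate and threshold contracts hold", {
  toy <- toy_two_group(matrix(1:4, 2), matrix(5:8, 2))
  toy$design$treatment <- c("R0", "R0", "S1", "S2")
  expect_error(nb_test(toy$counts, toy$design, "R0", "S1"),
               ">= 2 replicates")
})

test_that("log2 fold changes are recovered near the planted effect", {
  set.seed(5)
  n_null <- 270
  n_planted <- 30
  A <- matrix(rnbinom(5 * (n_null + n_planted), mu = 80, size = 20),
              n_null + n_planted, 5)
  B <- rbind(matrix(rnbinom(5 * n_null, mu = 80, size = 20), n_null, 5),
             matrix(rnbinom(5 * n_planted, mu = 320, size = 20),
                    n_planted, 5))
  toy <- toy_two_group(A, B)
  res <- nb_test(toy$counts, toy$design, "R0", "S1")
  planted <- res$log2fc[(n_null + 1):(n_null + n_planted)]
  expect_lt(median(abs(planted - 2)), 0.25)
})

test_that("the BH-adjusted caller controls false positives under the global null", {
  set.seed(6)
  ngene <- 2000
  A <- matrix(rnbinom(5 * ngene, mu = 60, size = 20), ngene, 5)
  B <- matrix(rnbinom(5 * ngene, mu = 60, size = 20), ngene, 5)
  toy <- toy_two_group(A, B)
  res <- nb_test(toy$counts, toy$design, "R0", "S1")
  expect_lte(mean(res$call != "ns"), 0.05)
})

test_that("external contrast tables are read and called consistently", {
  dir <- withr::local_tempdir()
  tab <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        log2FoldChange = c(2.1, -1.5, 0.2),
                        padj = c(0.001, 0.2, 0.9))
  readr::write_tsv(tab, file.path(dir, "c.tsv"))
  res <- read_contrast(file.path(dir, "c.tsv"), "R0", "S1")
  expect_identical(res$call, c("up", "ns", "ns"))
})
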