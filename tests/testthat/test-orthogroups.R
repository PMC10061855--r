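write_og_file <- function(dir, rows,
                          species = c("AEX", "WW", "At", "Zm", "Pv")) {
  path <- file.path(dir, "Orthogroups.tsv")
  header <- paste(c("Orthogroup", species), collapse = "\t")
  writeLines(c(header, rows), path)
  path
}

test_that("orthogroup tables parse, trim and validate", {
  dir <- withr::local_tempdir()
  path <- write_og_file(dir, c(
    "OG1\ta1, a2\tw1\tt1\t\t",
    "OG2\ta3\t\tt2, t3\tz1\t",
    "OG3\t\tw2\t\t\tp1"))
  ogs <- load_orthogroups(path)
  expect_equal(dplyr::n_distinct(ogs$orthogroup), 3)
  expect_true(all(c("a1", "a2", "w1") %in% ogs$gene[ogs$orthogroup == "OG1"]))
  expect_false(any(grepl(" ", ogs$gene)))          # whitespace trimmed
  expect_equal(nrow(ogs[ogs$orthogroup == "OG3" & ogs$species == "AEX", ]), 0)

  dup <- write_og_file(dir, c("OG1\ta1\t\t\t\t", "OG2\ta1\t\t\t\t"))
  expect_error(load_orthogroups(dup), "multiple orthogroups")
})

# toy table exercising every Venn region
toy_partition <- function(include_singletons = TRUE) {
  dir <- withr::local_tempdir()
  path <- write_og_file(dir, c(
    "OG01\ta1\tw1\tt1\t\t",      # shared (all three parties)
    "OG02\ta2\tw2\t\t\t",        # focal_shared
    "OG03\ta3\t\t\t\t",          # ecotype_A_unique
    "OG04\t\tw3\t\t\t",          # ecotype_B_unique
    "OG05\ta4\t\tt2\t\t",        # ecotype_A_with_other
    "OG06\t\tw4\t\tz1\t",        # ecotype_B_with_other
    "OG07\t\t\t\t\tp1",          # other_only
    "OG08\ta5\tw5\tt3\t\t",      # no DMG members -> excluded
    "OG09\ta6\tw6\tt4\t\t"))     # shared via a different outgroup? t4 not DMG; a6,w6 DMG -> focal_shared
  ogs <- load_orthogroups(path)
  dmg <- list(AEX = c("a1", "a2", "a3", "a4", "a6", "a_lone"),
              WW = c("w1", "w2", "w3", "w4", "w6"),
              At = c("t1", "t2"), Zm = c("z1"), Pv = c("p1"))
  list(ogs = ogs,
       part = partition_orthogroups(ogs, dmg, focal = c("AEX", "WW"),
                                    outgroups = c("At", "Zm", "Pv"),
                                    include_singletons = include_singletons),
       dmg = dmg)
}

test_that("tier assignment matches brute-force set algebra on the toy table", {
  tp <- toy_partition()
  part <- tp$part
  tier_of <- function(og) part$tier[part$orthogroup == og]
  expect_identical(tier_of("OG01"), "shared")
  expect_identical(tier_of("OG02"), "focal_shared")
  expect_identical(tier_of("OG03"), "ecotype_A_unique")
  expect_identical(tier_of("OG04"), "ecotype_B_unique")
  expect_identical(tier_of("OG05"), "ecotype_A_with_other")
  expect_identical(tier_of("OG06"), "ecotype_B_with_other")
  expect_identical(tier_of("OG07"), "other_only")
  expect_false("OG08" %in% part$orthogroup)
  expect_identical(tier_of("OG09"), "focal_shared")

  # independent brute-force Venn over the same inputs
  ogs <- tp$ogs; dmg <- tp$dmg
  for (og in unique(ogs$orthogroup)) {
    sub <- ogs[ogs$orthogroup == og, ]
    hasA <- any(sub$gene[sub$species == "AEX"] %in% dmg$AEX)
    hasB <- any(sub$gene[sub$species == "WW"] %in% dmg$WW)
    hasO <- any(mapply(function(sp, g) g %in% dmg[[sp]],
                       sub$species, sub$gene) &
                  !sub$species %in% c("AEX", "WW"))
    expected <- if (hasA && hasB && hasO) "shared"
      else if (hasA && hasB) "focal_shared"
      else if (hasA && hasO) "ecotype_A_with_other"
      else if (hasB && hasO) "ecotype_B_with_other"
      else if (hasA) "ecotype_A_unique"
      else if (hasB) "ecotype_B_unique"
      else if (hasO) "other_only" else NA_character_
    if (is.na(expected)) {
      expect_false(og %in% part$orthogroup)
    } else {
      expect_identical(tier_of(og), expected)
    }
  }
})

test_that("venn counts tally tiers, including flagged singletons", {
  part <- toy_partition()$part
  vc <- venn_counts(part)
  expect_identical(vc[["shared"]], 1L)
  expect_identical(vc[["focal_shared"]], 2L)
  expect_identical(vc[["ecotype_A_unique"]], 2L)    # OG03 + singleton a_lone
  expect_identical(sum(vc), nrow(part))
  expect_true(any(part$singleton))
  expect_identical(sum(venn_counts(toy_partition(FALSE)$part)), 8L)
  expect_true(all(venn_counts(part[0, ]) == 0L))
})

test_that("partitioning is invariant to column order and validates species", {
  tp <- toy_partition()
  ogs_shuffled <- dplyr::arrange(tp$ogs, dplyr::desc(gene))
  part2 <- partition_orthogroups(ogs_shuffled, tp$dmg,
                                 focal = c("AEX", "WW"),
                                 outgroups = c("At", "Zm", "Pv"))
  cols <- c("orthogroup", "tier", "has_A", "has_B", "has_other", "singleton")
  a <- dplyr::arrange(tibble::as_tibble(tp$part)[cols], orthogroup)
  b <- dplyr::arrange(tibble::as_tibble(part2)[cols], orthogroup)
  expect_equal(unclass(a)[cols], unclass(b)[cols])
  ga <- dplyr::arrange(attr(tp$part, "genes"), gene)
  gb <- dplyr::arrange(attr(part2, "genes"), gene)
  expect_equal(ga$tier, gb$tier)
  expect_equal(ga$gene, gb$gene)
  expect_error(partition_orthogroups(tp$ogs, tp$dmg,
                                     focal = c("AEX", "nope"),
                                     outgroups = "At"),
               "not present")
})

test_that("gene projection returns each ecotype's genes per tier", {
  tp <- toy_partition()
  expect_identical(hierarchy_genes(tp$part, "AEX", "shared"), "a1")
  expect_identical(hierarchy_genes(tp$part, "WW", "focal_shared"),
                   c("w2", "w6"))
  expect_identical(hierarchy_genes(tp$part, "AEX", "ecotype_A_unique"),
                   c("a3", "a_lone"))
})
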