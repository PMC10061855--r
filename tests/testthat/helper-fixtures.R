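# shared fixture builders; everything is generated in code

# proportions placing every gene in `none` (switch modules then carve their
# members out of that pool)
none_only_props <- c("[+/+]" = 0, "[-/-]" = 0, "[+/-]" = 0, "[-/+]" = 0,
                     "[+/=]" = 0, "[-/=]" = 0, "[=/+]" = 0, "[=/-]" = 0,
                     "none" = 1)

# minimal two-group count tibble + design for DE tests
toy_two_group <- function(countsA, countsB, genes = NULL) {
  nA <- ncol(countsA); nB <- ncol(countsB)
  m <- cbind(countsA, countsB)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- c(sprintf("A_%d", seq_len(nA)), sprintf("B_%d", seq_len(nB)))
  counts <- dplyr::bind_cols(tibble::tibble(gene = genes),
                             tibble::as_tibble(m))
  design <- tibble::tibble(sample = colnames(m), ecotype = "AEX",
                           treatment = rep(c("R0", "S1"), c(nA, nB)),
                           replicate = c(seq_len(nA), seq_len(nB)))
  list(counts = counts, design = design)
}

# leaf-weight records with chosen masses replicated per group
weights_record <- function(FW, TW, wilted, DW, ecotype = "AEX",
                           stage = "R0", n = 1) {
  tibble::tibble(sample_id = sprintf("%s_%s_%d", ecotype, stage, seq_len(n)),
                 ecotype = ecotype, stage = stage,
                 FW = FW, TW = TW, wilted_weight = wilted, DW = DW)
}

# all permutations of a vector (for the exhaustive correlation oracle)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# brute-force upper-tail hypergeometric by enumerating every draw
enum_hypergeom <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# definitional BH step-up, independent of stats::p.adjust
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# brute-force MCC: enumerate every vertex subset, keep maximal cliques
brute_mcc <- function(adj) {
  n <- nrow(adj)
  nodes <- seq_len(n)
  is_clique <- function(s) {
    if (length(s) < 2) return(FALSE)
    all(adj[s, s][upper.tri(adj[s, s])] == 1)
  }
  cliques <- list()
  for (size in 2:n) {
    for (s in utils::combn(n, size, simplify = FALSE)) {
      if (is_clique(s)) cliques[[length(cliques) + 1]] <- s
    }
  }
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(nodes, s),
                function(v) is_clique(sort(c(s, v))), logical(1)))
  }, cliques)
  mcc <- numeric(n)
  for (cl in maximal) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  mcc
}

# brute-force switch grouping: naive per-target signature map
brute_modules <- function(edges, min_size = 5) {
  sig <- tapply(seq_len(nrow(edges)), edges$target, function(i) {
    paste(sort(paste0(edges$tf[i], ":", edges$sign[i])), collapse = "|")
  })
  groups <- split(names(sig), unname(sig))
  keep <- Filter(function(g) {
    s <- sig[[g[1]]]
    parts <- strsplit(s, "|", fixed = TRUE)[[1]]
    has_pos <- any(grepl(":\\+$", parts))
    has_neg <- any(grepl(":-$", parts))
    has_pos && has_neg && length(g) >= min_size
  }, groups)
  lapply(unname(keep), sort)
}
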