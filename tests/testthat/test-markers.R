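norm_matrix <- function(values, spots, genes) {
  m <- matrix(values, nrow = length(spots),
              dimnames = list(spots, genes))
  m
}

test_that("rank-sum markers: exact p values and fold changes on hand cases", {
  spots <- paste0("s", 1:6)
  g1 <- spots[1:3]; g2 <- spots[4:6]
  # gene A fully separated: exact two-sided p = 2 / C(6,3) = 0.1
  # gene B identical across groups: log_fc 0, p 1
  m <- norm_matrix(c(5, 6, 7, 1, 2, 3,
                     2, 2, 2, 2, 2, 2), spots, c("A", "B"))
  tab <- wilcoxon_markers(m, g1, g2)
  expect_equal(tab$p[tab$gene == "A"], 0.1)
  expect_equal(tab$log_fc[tab$gene == "A"], log(3), tolerance = 1e-6)
  expect_equal(tab$p[tab$gene == "B"], 1)
  expect_equal(tab$log_fc[tab$gene == "B"], 0, tolerance = 1e-6)
  expect_true(all(tab$p_adj >= tab$p - 1e-15))
  expect_error(wilcoxon_markers(m, g1, c(g2, g1[1])), "disjoint")
  expect_error(wilcoxon_markers(m, g1[1], g2), ">= 2")
})

test_that("exact p values agree with enumeration of all 3v3 rank splits", {
  # brute-force null: all C(6,3) assignments of ranks to group 1
  enum_p <- function(x, y) {
    ranks <- rank(c(x, y))
    W_obs <- sum(ranks[1:3]) - 6  # Mann-Whitney U of group 1
    splits <- combn(6, 3)
    W_all <- apply(splits, 2, function(ix) sum(ranks[ix])) - 6
    mean(abs(W_all - 4.5) >= abs(W_obs - 4.5))
  }
  cases <- list(c(5, 6, 7, 1, 2, 3), c(1, 5, 6, 2, 3, 7),
                c(10, 2, 8, 4, 6, 12), c(1, 2, 7, 3, 5, 9))
  for (v in cases) {
    m <- norm_matrix(v, paste0("s", 1:6), "G")
    tab <- wilcoxon_markers(m, paste0("s", 1:3), paste0("s", 4:6))
    expect_equal(tab$p, enum_p(v[1:3], v[4:6]), tolerance = 1e-12)
  }
})

test_that("threshold filter applies the three rules with strict inequalities", {
  tab <- data.frame(
    gene = paste0("G", 1:6),
    log_fc = c(1.0, 0.25, 1.0, 1.0, -2.0, 0.8),
    pct1 = c(0.50, 0.50, 0.04, 0.50, 0.60, 0.30),
    pct2 = c(0.10, 0.10, 0.01, 0.10, 0.90, 0.10),
    p = c(1e-5, 1e-5, 1e-5, 0.5, 1e-5, 1e-6),
    p_adj = c(1e-4, 1e-4, 1e-4, 0.6, 1e-4, 1e-5))
  class(tab) <- c("marker_table", "data.frame")
  # G1 passes; G2 fails log_fc == 0.25 exactly; G3 fails pct 0.04;
  # G4 fails p_adj; G5 is down-regulated; G6 passes
  expect_setequal(filter_markers(tab), c("G1", "G6"))
  expect_setequal(filter_markers(tab, direction = "down"), "G5")
  # monotone in thresholds: loosening never removes a gene
  strict <- filter_markers(tab, min_pct = 0.2, min_log_fc = 0.9,
                           max_padj = 1e-4)
  loose <- filter_markers(tab, min_pct = 0.01, min_log_fc = 0.1,
                          max_padj = 0.05)
  expect_true(all(strict %in% loose))
})

test_that("type-I error of the marker test is calibrated on null data", {
  withr::with_seed(71, {
    n_genes <- 500
    m <- matrix(rpois(100 * n_genes, 5), nrow = 100,
                dimnames = list(paste0("s", 1:100), paste0("g", 1:n_genes)))
  })
  tab <- wilcoxon_markers(m, paste0("s", 1:50), paste0("s", 51:100))
  frac <- mean(tab$p < 0.05)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("planted fold-change markers are recovered with few false positives", {
  withr::with_seed(72, {
    n_genes <- 300
    planted <- paste0("g", 1:20)
    base <- matrix(rpois(80 * n_genes, 8), nrow = 80,
                   dimnames = list(paste0("s", 1:80), paste0("g", 1:n_genes)))
    base[1:40, planted] <- rpois(40 * 20, 16)  # fold change 2 in group 1
  })
  tab <- wilcoxon_markers(base, paste0("s", 1:40), paste0("s", 41:80))
  hits <- filter_markers(tab)
  expect_gte(sum(planted %in% hits), 0.9 * length(planted))
  false_pos <- setdiff(hits, planted)
  expect_lte(length(false_pos), 0.05 * length(hits) + 1)
})

test_that("marker depth curve hits the full-data count at p = 1", {
  withr::with_seed(73, {
    n <- 30; g <- 40
    counts <- matrix(rpois(n * g, 6), n,
                     dimnames = list(paste0("s", 1:n), paste0("g", 1:g)))
    counts[1:15, 1:5] <- rpois(15 * 5, 24)
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    rownames(coords) <- paste0("s", 1:n)
    recs <- which(counts > 0, arr.ind = TRUE)
    mt <- molecule_table(
      spot_id = rep(rownames(counts)[recs[, 1]], counts[recs]),
      gene_id = rep(colnames(counts)[recs[, 2]], counts[recs]),
      molecule_id = paste0("m", 1:sum(counts)),
      reads = 1 + rpois(sum(counts), 1))
  })
  ds <- collapse_molecules(mt, coords)
  norm <- normalize_median(ds)
  full_n <- length(filter_markers(
    wilcoxon_markers(norm, paste0("s", 1:15), paste0("s", 16:30))))
  curve <- marker_depth_curve(list(sim = mt), list(sim = coords),
                              paste0("s", 1:15), paste0("s", 16:30),
                              proportions = c(0.3, 1), seed = 2)
  expect_equal(curve$n_markers[curve$proportion == 1], full_n)
  expect_true(all(curve$n_markers >= 0))
})

test_that("marker intersection partitions the union by membership", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("g2"))
  res <- marker_intersection(sets)
  expect_equal(unname(res$tier_counts),
               c(1L, 0L, 2L))  # all-shared g2; unique g1, g3
  expect_equal(res$membership$signature[res$membership$gene == "g2"], "A&B&C")
  # identical sets -> everything all-shared; disjoint -> all unique
  same <- marker_intersection(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(unname(same$tier_counts["all_shared"]), 2L)
  disj <- marker_intersection(list(A = "x", B = "y", C = "z"))
  expect_equal(unname(disj$tier_counts["unique"]), 3L)
  expect_error(marker_intersection(list(A = "x")), ">= 2")
})
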