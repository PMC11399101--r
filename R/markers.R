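#' Rank-sum marker statistics between two spot groups
#'
#' For every gene, compares normalized expression between the two groups
#' with a two-sided Wilcoxon rank-sum test — exact when the combined group
#' size is <= 25 and the gene has no ties, otherwise the normal
#' approximation with tie and continuity correction. The log fold change
#' is the natural log of the ratio of group means with a small
#' pseudo-value: `ln((mean1 + eps) / (mean2 + eps))`, `eps = 1e-9`.
#' P values are Benjamini-Hochberg adjusted across all tested genes.
#'
#' @param norm sparse or dense spots x genes matrix of normalized values
#'   (see [normalize_median()])
#' @param group1,group2 disjoint character vectors of spot ids, each of
#'   size >= 2; `group1` is the group markers are "up" in
#' @return data.frame of class `marker_table` with columns
#'   `gene, log_fc, pct1, pct2, p, p_adj`
#' @export
wilcoxon_markers <- function(norm, group1, group2) {
  if (length(intersect(group1, group2))) stop("groups must be disjoint")
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs >= 2 spots")
  }
  missing <- setdiff(c(group1, group2), rownames(norm))
  if (length(missing)) {
    stop("spot(s) absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  m1 <- as.matrix(norm[group1, , drop = FALSE])
  m2 <- as.matrix(norm[group2, , drop = FALSE])
  eps <- 1e-9
  n1 <- length(group1); n2 <- length(group2)
  exact_ok <- (n1 + n2) <= 25
  res <- vapply(seq_len(ncol(m1)), function(g) {
    x <- m1[, g]; y <- m2[, g]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
      p <- 1  # gene constant across both groups: no evidence by definition
    } else {
      has_ties <- anyDuplicated(c(x, y)) > 0
      p <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = "two.sided",
        exact = exact_ok && !has_ties, correct = TRUE)$p.value)
    }
    c(log(mean(x) + eps) - log(mean(y) + eps),
      mean(x > 0), mean(y > 0), p)
  }, numeric(4))
  out <- data.frame(gene = colnames(norm), log_fc = res[1, ],
                    pct1 = res[2, ], pct2 = res[3, ], p = res[4, ],
                    p_adj = stats::p.adjust(res[4, ], method = "BH"),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Threshold filter for marker genes
#'
#' Applies the three-part marker definition: detection in more than
#' `min_pct` of the up-regulated group's spots, log fold change greater
#' than `min_log_fc`, and adjusted P value below `max_padj` — all strict
#' inequalities. With `direction = "up"` (default) genes must be enriched
#' in group 1; `"down"` selects the mirror image.
#'
#' @param table a `marker_table` from [wilcoxon_markers()]
#' @param min_pct detection-fraction threshold (default 0.05)
#' @param min_log_fc log fold-change threshold (default 0.25)
#' @param max_padj adjusted-P threshold (default 0.01)
#' @param direction `"up"` or `"down"`
#' @return character vector of qualifying gene ids
#' @export
filter_markers <- function(table, min_pct = 0.05, min_log_fc = 0.25,
                           max_padj = 0.01, direction = c("up", "down")) {
  stopifnot(inherits(table, "marker_table"))
  direction <- match.arg(direction)
  if (min_pct < 0 || min_pct > 1 || max_padj <= 0 || max_padj > 1) {
    stop("thresholds out of range")
  }
  if (direction == "up") {
    keep <- table$pct1 > min_pct & table$log_fc > min_log_fc &
      table$p_adj < max_padj
  } else {
    keep <- table$pct2 > min_pct & table$log_fc < -min_log_fc &
      table$p_adj < max_padj
  }
  table$gene[keep]
}

#' Marker counts as a function of sequencing depth
#'
#' For each platform and read proportion: downsample the molecule table,
#' re-quantify to counts, re-apply QC filtering and median normalization,
#' rerun the rank-sum test between the two groups (restricted to surviving
#' spots) and count the genes passing [filter_markers()].
#'
#' @param molecules named list of `molecule_table`s, one per platform
#' @param coords named list (same names) of spot coordinate matrices with
#'   spot ids as rownames
#' @param group1,group2 spot-id groups defined on the full data
#' @param proportions read proportions in (0, 1]
#' @param seed integer seed
#' @param ... thresholds forwarded to [filter_markers()]
#' @return data.frame `platform, proportion, reads, n_markers`
#' @export
marker_depth_curve <- function(molecules, coords, group1, group2,
                               proportions = seq(0.2, 1, by = 0.2),
                               seed = 1L, ...) {
  stopifnot(is.list(molecules), !is.null(names(molecules)))
  if (any(proportions <= 0 | proportions > 1)) {
    stop("proportions must lie in (0, 1]")
  }
  rows <- list()
  for (pi in seq_along(names(molecules))) {
    nm <- names(molecules)[pi]
    mt <- molecules[[nm]]
    R <- total_reads(mt)
    for (qi in seq_along(proportions)) {
      p <- proportions[qi]
      target <- floor(p * R + 0.5)
      sub <- downsample_reads(mt, target,
                              seed = seed + pi * 1000L + qi)
      n_mark <- if (nrow(sub) == 0) 0L else {
        ds <- collapse_molecules(sub, coords[[nm]])
        totals <- spot_totals(ds)
        ds <- subset_spots(ds, totals > 0)
        norm <- normalize_median(ds)
        g1 <- intersect(group1, rownames(norm))
        g2 <- intersect(group2, rownames(norm))
        if (length(g1) < 2 || length(g2) < 2) 0L else {
          length(filter_markers(wilcoxon_markers(norm, g1, g2), ...))
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        platform = nm, proportion = p, reads = target, n_markers = n_mark,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Partition gene sets by membership signature
#'
#' Assigns every gene in the union of the named sets to its exact
#' membership signature (which sets contain it) and tallies genes per
#' signature and per sharing tier — shared by all sets, shared by a strict
#' subset of >= 2, or unique to one set.
#'
#' @param sets named list of >= 2 character vectors
#' @return list with `membership` (data.frame `gene, signature, n_sets`)
#'   and `tier_counts` (named vector: `all_shared`, `partially_shared`,
#'   `unique`)
#' @export
marker_intersection <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || is.null(names(sets))) {
    stop("need >= 2 named gene sets")
  }
  genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(sets)))
  n_sets <- rowSums(member)
  signature <- apply(member, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  tier <- ifelse(n_sets == length(sets), "all_shared",
                 ifelse(n_sets > 1, "partially_shared", "unique"))
  tiers <- c(all_shared = sum(tier == "all_shared"),
             partially_shared = sum(tier == "partially_shared"),
             unique = sum(tier == "unique"))
  list(membership = data.frame(gene = genes, signature = signature,
                               n_sets = n_sets, tier = tier,
                               row.names = NULL, stringsAsFactors = FALSE),
       tier_counts = tiers)
}
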