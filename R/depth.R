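#' Downsample sequencing reads in a molecule table
#'
#' Draws exactly `target_reads` reads uniformly without replacement from
#' the pooled reads of all molecules (equivalent to selecting reads by
#' read ID). A molecule survives iff at least one of its reads is drawn;
#' surviving molecules carry their retained read counts. The per-molecule
#' retained counts follow the multivariate hypergeometric distribution.
#'
#' An alternative `"binomial"` mode thins each read independently with
#' probability `target_reads / total_reads`; the output read total is then
#' itself random. The default without-replacement mode is what
#' depth-matching between platforms requires.
#'
#' @param mt a `molecule_table`
#' @param target_reads integer in `[0, total_reads(mt)]`
#' @param seed integer seed
#' @param mode `"hypergeometric"` (without replacement, exact total) or
#'   `"binomial"` (independent thinning)
#' @return a `molecule_table` of the surviving molecules
#' @export
downsample_reads <- function(mt, target_reads, seed,
                             mode = c("hypergeometric", "binomial")) {
  stopifnot(inherits(mt, "molecule_table"))
  mode <- match.arg(mode)
  R <- total_reads(mt)
  if (target_reads < 0 || target_reads > R) {
    stop("target_reads must lie in [0, ", R, "]")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  if (mode == "binomial") {
    kept <- stats::rbinom(nrow(mt), mt$reads, target_reads / R)
  } else {
    # draw read ids 1..R without replacement, map back to their molecules
    idx <- sample.int(R, target_reads)
    ends <- cumsum(mt$reads)
    mol <- findInterval(idx - 0.5, c(0, ends))
    kept <- tabulate(mol, nbins = nrow(mt))
  }
  out <- mt[kept > 0, , drop = FALSE]
  out$reads <- kept[kept > 0]
  class(out) <- c("molecule_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Downsample several platforms to a common read depth
#'
#' Matches sequencing depth across samples: every table is downsampled
#' (without replacement) to the minimum total read count among the inputs,
#' so that downstream sensitivity comparisons are not confounded by depth.
#'
#' @param mts named list of >= 2 `molecule_table`s
#' @param seed integer seed; each table uses `seed + its index`
#' @return named list of downsampled `molecule_table`s, all with equal
#'   `total_reads`
#' @export
downsample_to_common_depth <- function(mts, seed = 1L) {
  if (!is.list(mts) || length(mts) < 2) {
    stop("need at least 2 molecule tables to depth-match")
  }
  depth <- min(vapply(mts, total_reads, numeric(1)))
  out <- lapply(seq_along(mts), function(i) {
    downsample_reads(mts[[i]], depth, seed = seed + i)
  })
  names(out) <- names(mts)
  out
}

#' Build a UMI saturation curve
#'
#' For each proportion `p`, downsamples the read pool to
#' `round(p * total_reads)` reads (round half up) `n_rep` times and
#' records the mean and s.d. of the number of distinct surviving molecules
#' (UMIs). The curve plateaus when most molecules have been sequenced at
#' least once — the saturation behavior depth comparisons rest on.
#'
#' @param mt a `molecule_table`
#' @param proportions strictly increasing values in (0, 1]
#' @param n_rep replicates per proportion (>= 1)
#' @param seed integer seed
#' @return data.frame of class `saturation_curve` with columns
#'   `p, reads, mean_umis, sd_umis, n_rep`
#' @export
saturation_curve <- function(mt, proportions = seq(0.1, 1, by = 0.1),
                             n_rep = 10L, seed = 1L) {
  stopifnot(inherits(mt, "molecule_table"))
  if (any(proportions <= 0 | proportions > 1)) {
    stop("proportions must lie in (0, 1]")
  }
  proportions <- sort(unique(proportions))
  if (n_rep < 1) stop("n_rep must be >= 1")
  R <- total_reads(mt)
  rows <- lapply(seq_along(proportions), function(i) {
    p <- proportions[i]
    target <- floor(p * R + 0.5)  # round half up
    umis <- vapply(seq_len(n_rep), function(rep) {
      nrow(downsample_reads(mt, target, seed = seed + (i - 1L) * n_rep + rep))
    }, numeric(1))
    data.frame(p = p, reads = target, mean_umis = mean(umis),
               sd_umis = if (n_rep > 1) stats::sd(umis) else 0,
               n_rep = n_rep)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("saturation_curve", "data.frame")
  out
}

#' Expected surviving UMIs under read downsampling
#'
#' Closed-form expectation of the number of distinct molecules retained
#' when `target_reads` reads are drawn without replacement from the pool:
#' `sum_m [1 - C(R - r_m, T) / C(R, T)]` with `R` the read total, `r_m`
#' each molecule's reads and `T = target_reads`. Serves as the analytic
#' reference for the stochastic downsampler.
#'
#' @param mt a `molecule_table`
#' @param target_reads integer in `[0, total_reads(mt)]`
#' @return expected number of surviving molecules
#' @export
expected_umis <- function(mt, target_reads) {
  stopifnot(inherits(mt, "molecule_table"))
  R <- total_reads(mt)
  if (target_reads < 0 || target_reads > R) {
    stop("target_reads must lie in [0, ", R, "]")
  }
  if (target_reads == 0) return(0)
  # log-space survival probabilities for numerical stability
  p_lost <- exp(lchoose(R - mt$reads, target_reads) - lchoose(R, target_reads))
  p_lost[R - mt$reads < target_reads] <- 0
  sum(1 - p_lost)
}
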