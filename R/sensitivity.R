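#' Total UMI count of a dataset
#'
#' Sum of all entries of the count matrix — the headline sensitivity
#' statistic for a region of interest (apply [select_roi()] first to
#' restrict to a region).
#'
#' @param ds a `spatial_counts` object
#' @return integer-valued total
#' @export
roi_total_umi <- function(ds) {
  stopifnot(inherits(ds, "spatial_counts"))
  sum(ds$counts)
}

#' Define a set of rectangular windows
#'
#' Axis-aligned rectangles (by convention 50 x 50 um, the coarsest spot
#' pitch among compared platforms) used to sum marker-gene UMIs in
#' morphologically matched locations.
#'
#' @param x0,y0 numeric vectors of lower-left corners (um)
#' @param width_um,height_um window sizes (recycled; default 50)
#' @return data.frame of class `window_set`
#' @export
window_set <- function(x0, y0, width_um = 50, height_um = 50) {
  if (any(width_um <= 0) || any(height_um <= 0)) {
    stop("window sizes must be positive")
  }
  ws <- data.frame(x0 = x0, y0 = y0, width_um = width_um,
                   height_um = height_um)
  class(ws) <- c("window_set", "data.frame")
  ws
}

#' Marker-gene UMI sums in fixed windows
#'
#' For each window, sums the counts of the listed genes over spots whose
#' centers lie in the half-open rectangle
#' `[x0, x0 + width) x [y0, y0 + height)`; reports per-window sums plus
#' their mean and sample standard deviation across windows.
#'
#' @param ds a `spatial_counts` object
#' @param genes character vector of gene ids present in `ds`
#' @param windows a [window_set()]
#' @return list with `per_window` (numeric vector), `mean`, `sd`
#' @export
window_marker_sum <- function(ds, genes, windows) {
  stopifnot(inherits(ds, "spatial_counts"), inherits(windows, "window_set"))
  unknown <- setdiff(genes, colnames(ds$counts))
  if (length(unknown)) {
    stop("gene(s) not in dataset: ", paste(unknown, collapse = ", "))
  }
  per_spot <- Matrix::rowSums(ds$counts[, genes, drop = FALSE])
  x <- ds$coords[, "x_um"]; y <- ds$coords[, "y_um"]
  sums <- vapply(seq_len(nrow(windows)), function(w) {
    inw <- x >= windows$x0[w] & x < windows$x0[w] + windows$width_um[w] &
           y >= windows$y0[w] & y < windows$y0[w] + windows$height_um[w]
    sum(per_spot[inw])
  }, numeric(1))
  list(per_window = sums, mean = mean(sums),
       sd = if (length(sums) > 1) stats::sd(sums) else 0)
}

#' Compare capture sensitivity across platforms
#'
#' Computes, per platform, the ROI total UMI count and the window
#' marker-gene statistics, optionally after downsampling all platforms to
#' a common read depth (which requires molecule tables). Platforms are
#' ranked by mean window marker sum, descending; ties break by ROI total,
#' then platform name.
#'
#' @param datasets named list of `spatial_counts` (already ROI-selected,
#'   or whole datasets)
#' @param windows a [window_set()]
#' @param genes marker genes to sum in the windows
#' @param molecules optional named list of `molecule_table`s matching
#'   `datasets`, required when `common_depth = TRUE`
#' @param common_depth if TRUE, depth-match all platforms first
#' @param seed seed used for the depth-matching downsample
#' @return data.frame with one row per platform: `platform, total_umi,
#'   window_mean, window_sd, n_windows, rank`
#' @export
compare_platforms_sensitivity <- function(datasets, windows, genes,
                                          molecules = NULL,
                                          common_depth = FALSE, seed = 1L) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  if (is.null(names(datasets))) stop("datasets must be named by platform")
  if (common_depth) {
    if (is.null(molecules)) {
      stop("common_depth requires molecule tables for every platform")
    }
    molecules <- molecules[names(datasets)]
    # reads are depth-matched within the selected spots only
    molecules <- lapply(names(datasets), function(nm) {
      mt <- molecules[[nm]]
      keep <- mt$spot_id %in% rownames(datasets[[nm]]$coords)
      out <- mt[keep, , drop = FALSE]
      class(out) <- c("molecule_table", "data.frame")
      out
    })
    names(molecules) <- names(datasets)
    if (length(datasets) >= 2) {
      molecules <- downsample_to_common_depth(molecules, seed = seed)
    }
    datasets <- lapply(names(datasets), function(nm) {
      collapse_molecules(molecules[[nm]], datasets[[nm]]$coords,
                         gene_ids = colnames(datasets[[nm]]$counts),
                         platform = datasets[[nm]]$platform)
    })
    names(datasets) <- names(molecules)
  }
  rows <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    wm <- window_marker_sum(ds, genes, windows)
    data.frame(platform = nm, total_umi = roi_total_umi(ds),
               window_mean = wm$mean, window_sd = wm$sd,
               n_windows = nrow(windows), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$window_mean, -out$total_umi, out$platform)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}
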