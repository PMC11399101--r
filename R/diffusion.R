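#' Define a strip (modality) for 1-D intensity profiling
#'
#' A rectangular strip laid across a histological boundary: spots within
#' `width_um / 2` of the axis line are projected onto the axis and binned,
#' yielding a 1-D expression profile whose left flank quantifies lateral
#' diffusion.
#'
#' @param anchor numeric (x, y): the strip origin in um
#' @param axis numeric (ux, uy): profile direction (normalized internally)
#' @param length_um strip length, an integer multiple of `bin_um`
#' @param width_um strip width (default 50)
#' @param bin_um bin size along the axis (default 10)
#' @return an object of class `strip`
#' @export
strip <- function(anchor, axis = c(1, 0), length_um, width_um = 50,
                  bin_um = 10) {
  if (length_um <= 0 || width_um <= 0 || bin_um <= 0) {
    stop("length_um, width_um, bin_um must be positive")
  }
  n_bins <- length_um / bin_um
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("length_um must be an integer multiple of bin_um")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a nonzero vector")
  structure(list(anchor = as.numeric(anchor), axis = as.numeric(axis) / nrm,
                 length_um = length_um, width_um = width_um, bin_um = bin_um),
            class = "strip")
}

#' Strip intensity profile of marker genes
#'
#' Projects spot centers onto the strip axis; spots within `width_um / 2`
#' of the axis line and within `[0, length_um)` along it contribute their
#' summed counts of `genes` to half-open bins of `bin_um`. The peak is the
#' (leftmost) argmax bin.
#'
#' @param ds a `spatial_counts` object
#' @param genes nonempty character vector of gene ids
#' @param s a [strip()]
#' @return an `intensity_profile`: list with `bin_centers`, `values`,
#'   `bin_um`, `peak_index` (NA when the profile is all zero),
#'   `normalized` flag
#' @export
strip_profile <- function(ds, genes, s) {
  stopifnot(inherits(ds, "spatial_counts"), inherits(s, "strip"))
  if (length(genes) == 0) stop("at least one gene is required")
  unknown <- setdiff(genes, colnames(ds$counts))
  if (length(unknown)) {
    stop("gene(s) not in dataset: ", paste(unknown, collapse = ", "))
  }
  per_spot <- Matrix::rowSums(ds$counts[, genes, drop = FALSE])
  dx <- ds$coords[, "x_um"] - s$anchor[1]
  dy <- ds$coords[, "y_um"] - s$anchor[2]
  along <- dx * s$axis[1] + dy * s$axis[2]
  across <- -dx * s$axis[2] + dy * s$axis[1]
  inside <- abs(across) <= s$width_um / 2 & along >= 0 & along < s$length_um
  n_bins <- as.integer(round(s$length_um / s$bin_um))
  values <- numeric(n_bins)
  if (any(inside)) {
    bin <- floor(along[inside] / s$bin_um) + 1
    tab <- tapply(per_spot[inside], bin, sum)
    values[as.integer(names(tab))] <- tab
  }
  intensity_profile(values, s$bin_um)
}

intensity_profile <- function(values, bin_um, normalized = FALSE) {
  n_bins <- length(values)
  structure(list(bin_centers = (seq_len(n_bins) - 0.5) * bin_um,
                 values = as.numeric(values), bin_um = bin_um,
                 peak_index = if (any(values > 0)) which.max(values) else NA_integer_,
                 normalized = normalized),
            class = "intensity_profile")
}

#' Align profiles on their peaks and average
#'
#' Modalities with total counts below `min_total` are dropped first (the
#' insufficient-counts filter). Remaining profiles are shifted so their
#' peak bins coincide, then averaged position-wise over the overlapping
#' support, which is truncated to the bins covered by every profile.
#'
#' @param profiles list of `intensity_profile`s with a common `bin_um`
#' @param min_total minimum total counts for a modality to be kept
#'   (default 10)
#' @return an `intensity_profile` of the aligned average
#' @export
align_and_average <- function(profiles, min_total = 10) {
  stopifnot(length(profiles) >= 1)
  bins <- unique(vapply(profiles, function(p) p$bin_um, numeric(1)))
  if (length(bins) != 1) stop("profiles must share bin_um")
  keep <- vapply(profiles, function(p) {
    sum(p$values) >= min_total && !is.na(p$peak_index)
  }, logical(1))
  profiles <- profiles[keep]
  if (!length(profiles)) stop("all modalities filtered out (insufficient counts)")
  peaks <- vapply(profiles, function(p) p$peak_index, integer(1))
  lens <- vapply(profiles, function(p) length(p$values), integer(1))
  left <- min(peaks - 1)          # bins available left of the peak in all
  right <- min(lens - peaks)      # bins available right of the peak in all
  rel <- seq(-left, right)
  mat <- vapply(seq_along(profiles), function(i) {
    profiles[[i]]$values[peaks[i] + rel]
  }, numeric(length(rel)))
  avg <- rowMeans(as.matrix(mat))
  intensity_profile(avg, bins)
}

#' Normalize a profile to unit area under the curve
#'
#' Rescales values so that `sum(values) * bin_um == 1`, putting platforms
#' with different absolute depths on a common density scale.
#'
#' @param profile an `intensity_profile` with positive total
#' @return the normalized `intensity_profile`
#' @export
normalize_auc <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  auc <- sum(profile$values) * profile$bin_um
  if (auc <= 0) stop("cannot normalize an all-zero profile")
  intensity_profile(profile$values / auc, profile$bin_um, normalized = TRUE)
}

#' Left width at half maximum (LWHM)
#'
#' The diffusion statistic: the distance from the profile peak leftward to
#' where intensity first falls to half the peak value. Scanning left from
#' the peak, the first bin with value strictly below half marks the
#' crossing; its position is linearly interpolated between that bin's
#' center and its right neighbor. Only the left side is used because
#' genuine expression may continue to the right of the chosen boundary.
#' Returns `NA` when no bin left of the peak drops below half (flat or
#' monotone-left profiles: the modality is excluded, not an error).
#'
#' @param profile an `intensity_profile` (non-normalized values are the
#'   convention, but LWHM is invariant to positive scaling)
#' @return LWHM in micrometres, or `NA` when undefined
#' @export
lwhm <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  peak <- profile$peak_index
  if (is.na(peak)) return(NA_real_)
  v <- profile$values
  half <- v[peak] / 2
  below <- which(v[seq_len(peak - 1)] < half)
  if (peak == 1 || !length(below)) return(NA_real_)
  b <- max(below)  # first bin below half when scanning left from the peak
  # linear interpolation between bin b and its right neighbor
  x0 <- profile$bin_centers[b]; x1 <- profile$bin_centers[b + 1]
  y0 <- v[b]; y1 <- v[b + 1]
  crossing <- x0 + (half - y0) / (y1 - y0) * (x1 - x0)
  profile$bin_centers[peak] - crossing
}

#' Per-platform LWHM summary over modalities
#'
#' Computes the LWHM of every modality (strip) per platform from
#' non-normalized counts, excludes undefined ones, and summarizes each
#' platform by median and interquartile range. Platforms are ranked by
#' median LWHM ascending: smaller widths mean tighter spatial confinement
#' (less lateral diffusion).
#'
#' @param datasets named list of `spatial_counts`, one per platform
#' @param strips named list (same names) of lists of [strip()]s
#' @param genes marker gene id(s) to profile
#' @param min_total insufficient-counts filter applied per modality
#' @return list with `per_modality` (data.frame `platform, modality,
#'   lwhm_um`) and `summary` (data.frame `platform, n_defined, median_lwhm,
#'   iqr_lwhm, rank`; platforms with no defined modality get rank `NA`)
#' @export
diffusion_summary <- function(datasets, strips, genes, min_total = 10) {
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  per <- do.call(rbind, lapply(names(datasets), function(nm) {
    ss <- strips[[nm]]
    vals <- vapply(seq_along(ss), function(k) {
      p <- strip_profile(datasets[[nm]], genes, ss[[k]])
      if (sum(p$values) < min_total) return(NA_real_)
      lwhm(p)
    }, numeric(1))
    data.frame(platform = nm, modality = seq_along(ss), lwhm_um = vals,
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(split(per, per$platform), function(d) {
    ok <- d$lwhm_um[!is.na(d$lwhm_um)]
    data.frame(platform = d$platform[1], n_defined = length(ok),
               median_lwhm = if (length(ok)) stats::median(ok) else NA_real_,
               iqr_lwhm = if (length(ok)) stats::IQR(ok, type = 7) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  if (any(summ$n_defined == 0)) {
    warning("platform(s) with no defined LWHM excluded from ranking: ",
            paste(summ$platform[summ$n_defined == 0], collapse = ", "))
  }
  ranked <- which(summ$n_defined > 0)
  summ$rank <- NA_integer_
  summ$rank[ranked[order(summ$median_lwhm[ranked], summ$platform[ranked])]] <-
    seq_along(ranked)
  list(per_modality = per, summary = summ)
}

#' Spatial dispersion of a sparsely expressed gene
#'
#' Identifies clusters of spots expressing `gene` with DBSCAN on spot
#' coordinates (noise points are discarded), then reports per cluster the
#' spot count, the mean expression, and the variance of member distances
#' — higher variance indicates counts smeared over dispersed locations,
#' i.e. diffusion of transcripts from what should be solitary cells.
#'
#' @param ds a `spatial_counts` object
#' @param gene gene id
#' @param eps_um DBSCAN neighborhood radius (default `2 * pitch_um` when
#'   the platform metadata carries a pitch, else required)
#' @param min_pts DBSCAN core-point threshold (default 3)
#' @param variance `"centroid"` (default): sample variance of member
#'   distances to the cluster centroid; `"pairwise"`: sample variance of
#'   all pairwise member distances
#' @return data.frame `cluster, n_spots, mean_count, distance_variance`
#'   (zero rows when no spot expresses the gene)
#' @export
dispersion_clusters <- function(ds, gene, eps_um = NULL, min_pts = 3,
                                variance = c("centroid", "pairwise")) {
  stopifnot(inherits(ds, "spatial_counts"))
  variance <- match.arg(variance)
  if (!gene %in% colnames(ds$counts)) stop("unknown gene: ", gene)
  if (is.null(eps_um)) {
    pitch <- ds$platform$pitch_um
    if (is.null(pitch) || is.na(pitch)) {
      stop("eps_um is required when platform pitch is unknown")
    }
    eps_um <- 2 * pitch
  }
  if (eps_um <= 0 || min_pts < 1) stop("eps_um > 0 and min_pts >= 1 required")
  counts <- ds$counts[, gene]
  expressing <- which(counts > 0)
  empty <- data.frame(cluster = integer(0), n_spots = integer(0),
                      mean_count = numeric(0), distance_variance = numeric(0))
  if (!length(expressing)) return(empty)
  xy <- ds$coords[expressing, , drop = FALSE]
  labels <- dbscan_labels(xy, eps_um, min_pts)
  keep <- labels > 0
  if (!any(keep)) return(empty)
  rows <- lapply(sort(unique(labels[keep])), function(cl) {
    idx <- which(labels == cl)
    pts <- xy[idx, , drop = FALSE]
    if (variance == "centroid") {
      ctr <- colMeans(pts)
      d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
    } else {
      d <- as.numeric(stats::dist(pts))
    }
    data.frame(cluster = cl, n_spots = length(idx),
               mean_count = mean(counts[expressing][idx]),
               distance_variance = if (length(d) > 1) stats::var(d) else 0)
  })
  do.call(rbind, rows)
}

# Plain DBSCAN (Euclidean, O(n^2) distance queries): 0 = noise, clusters
# numbered from 1. Suited to the few hundred expressing spots this
# analysis sees.
dbscan_labels <- function(xy, eps, min_pts) {
  n <- nrow(xy)
  d2 <- as.matrix(stats::dist(xy))^2
  eps2 <- eps^2
  neighbors <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps2))
  is_core <- vapply(neighbors, length, integer(1)) >= min_pts
  labels <- integer(n)      # 0 = unassigned/noise
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !is_core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in neighbors[[cur]]) {
        if (labels[nb] == 0L) labels[nb] <- cl
        if (!visited[nb] && is_core[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}
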