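#' Bin spots onto a regular grid
#'
#' Assigns each spot center to a half-open grid cell
#' `[k * bin_um, (k + 1) * bin_um)` on each axis and sums UMI counts per
#' cell. This is how high-resolution arrays are aggregated to a common
#' spot size (e.g. 10 um bins) for visual or cross-platform comparison.
#' The total UMI count is conserved exactly.
#'
#' @param ds a `spatial_counts` object
#' @param bin_um bin side length in micrometres, > 0
#' @return a `spatial_counts` object with one spot per occupied grid cell,
#'   coordinates at cell centers
#' @export
bin_spots <- function(ds, bin_um) {
  stopifnot(inherits(ds, "spatial_counts"))
  if (!is.numeric(bin_um) || length(bin_um) != 1 || bin_um <= 0) {
    stop("bin_um must be a positive number")
  }
  kx <- floor(ds$coords[, "x_um"] / bin_um)
  ky <- floor(ds$coords[, "y_um"] / bin_um)
  cell <- paste(kx, ky, sep = "_")
  ucell <- unique(cell)
  grp <- match(cell, ucell)
  agg <- Matrix::sparseMatrix(i = grp, j = seq_along(grp), x = 1,
                              dims = c(length(ucell), nrow(ds$counts)))
  counts <- agg %*% ds$counts
  first <- match(ucell, cell)
  coords <- cbind(x_um = (kx[first] + 0.5) * bin_um,
                  y_um = (ky[first] + 0.5) * bin_um)
  rownames(coords) <- paste0("bin_", ucell)
  spatial_counts(counts, coords, spot_ids = rownames(coords),
                 gene_ids = colnames(ds$counts), platform = ds$platform)
}

#' Select spots inside a region of interest
#'
#' Keeps the spots whose centers fall inside the ROI polygon, mirroring
#' manual delineation of tissue structures. Membership uses the even-odd
#' (ray crossing) rule; a center exactly on the boundary counts as inside.
#' The gene set is unchanged.
#'
#' @param ds a `spatial_counts` object
#' @param region an [roi()] object
#' @return a `spatial_counts` with the selected spots (possibly none)
#' @export
select_roi <- function(ds, region) {
  stopifnot(inherits(ds, "spatial_counts"), inherits(region, "roi"))
  keep <- points_in_polygon(ds$coords[, "x_um"], ds$coords[, "y_um"],
                            region$polygon)
  subset_spots(ds, keep)
}

# Even-odd rule with on-edge treated as inside.
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  vapply(seq_along(x), function(i) {
    x0 <- x[i]; y0 <- y[i]
    inside <- FALSE
    for (e in seq_len(n)) {
      ax <- px[e]; ay <- py[e]; bx <- qx[e]; by <- qy[e]
      # on-segment test
      cr <- (bx - ax) * (y0 - ay) - (by - ay) * (x0 - ax)
      if (abs(cr) < 1e-9 * max(1, abs(bx - ax), abs(by - ay)) &&
          x0 >= min(ax, bx) - 1e-12 && x0 <= max(ax, bx) + 1e-12 &&
          y0 >= min(ay, by) - 1e-12 && y0 <= max(ay, by) + 1e-12) {
        return(TRUE)
      }
      if ((ay > y0) != (by > y0)) {
        xint <- ax + (y0 - ay) / (by - ay) * (bx - ax)
        if (x0 < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Filter low-quality spots
#'
#' Removes spots whose total UMI count falls below 30% of the first
#' quartile (25th percentile, type-7 interpolation) of per-spot totals.
#' This is the quality-control step applied before normalization and
#' clustering.
#'
#' @param ds a `spatial_counts` object with at least 4 spots
#' @param fraction multiplier on the first quartile (default 0.3)
#' @return the filtered `spatial_counts`
#' @export
filter_low_quality <- function(ds, fraction = 0.3) {
  stopifnot(inherits(ds, "spatial_counts"))
  totals <- spot_totals(ds)
  if (length(totals) < 4) stop("need >= 4 spots for a stable first quartile")
  q1 <- stats::quantile(totals, 0.25, type = 7, names = FALSE)
  subset_spots(ds, totals >= fraction * q1)
}

#' Median-of-totals normalization
#'
#' Scales each spot's counts so that every spot sums to the median of the
#' per-spot totals: `value[s, g] = counts[s, g] / total[s] * median(totals)`.
#' The median total acts as the per-platform scaling factor, so normalized
#' values are comparable across spots within a platform.
#'
#' @param ds a `spatial_counts` object; every spot total must be positive
#'   (run [filter_low_quality()] first)
#' @return a sparse real matrix (spots x genes) of normalized values, with
#'   the median total attached as attribute `scale_factor`
#' @export
normalize_median <- function(ds) {
  stopifnot(inherits(ds, "spatial_counts"))
  totals <- spot_totals(ds)
  if (any(totals == 0)) {
    bad <- names(totals)[totals == 0][1]
    stop("spot '", bad, "' has zero total counts; filter before normalizing")
  }
  med <- stats::median(totals)
  norm <- Matrix::Diagonal(x = med / totals) %*% ds$counts
  dimnames(norm) <- dimnames(ds$counts)
  attr(norm, "scale_factor") <- med
  norm
}
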