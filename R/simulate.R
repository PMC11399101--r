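#' Define a synthetic tissue layout
#'
#' Two layout families cover the geometries the benchmark analyses assume:
#' `"eye_rings"` — concentric rings around a center, emulating an embryonic
#' eye (lens enveloped by neural retina and melanocyte layers) — and
#' `"layers"` — parallel bands along the y axis, emulating laminated
#' structures such as cortex or olfactory bulb. Every in-bounds point
#' resolves to exactly one region; points outside the outermost ring or
#' the last boundary belong to the final "outside" region.
#'
#' @param kind `"eye_rings"` or `"layers"`
#' @param params for `eye_rings`: `center` (x, y) and `radii`, a strictly
#'   increasing vector; for `layers`: `boundaries`, a strictly increasing
#'   vector of y cut points.
#' @param region_labels unique labels, one per region:
#'   `length(radii) + 1` for rings (last = outside),
#'   `length(boundaries) - 1` for layers (bands between consecutive cuts;
#'   points outside the outer boundaries resolve to `NA`).
#' @return an object of class `tissue_layout` with a `region_of(x, y)`
#'   function element
#' @export
make_layout <- function(kind = c("eye_rings", "layers"), params,
                        region_labels = NULL) {
  kind <- match.arg(kind)
  if (kind == "eye_rings") {
    radii <- params$radii
    if (is.null(radii) || any(diff(radii) <= 0) || any(radii <= 0)) {
      stop("ring radii must be positive and strictly increasing")
    }
    center <- params$center %||% c(0, 0)
    n_reg <- length(radii) + 1
    if (is.null(region_labels)) {
      region_labels <- c(paste0("ring", seq_along(radii)), "outside")
    }
    if (length(region_labels) != n_reg || anyDuplicated(region_labels)) {
      stop("need ", n_reg, " unique region labels")
    }
    region_of <- function(x, y) {
      r <- sqrt((x - center[1])^2 + (y - center[2])^2)
      region_labels[findInterval(r, radii, left.open = TRUE) + 1]
    }
  } else {
    bnd <- params$boundaries
    if (is.null(bnd) || length(bnd) < 2 || any(diff(bnd) <= 0)) {
      stop("layer boundaries must be strictly increasing (>= 2 values)")
    }
    # k boundaries delimit k - 1 layers; points outside [b1, bk) -> NA
    n_reg <- length(bnd) - 1
    if (is.null(region_labels)) region_labels <- paste0("layer", seq_len(n_reg))
    if (length(region_labels) != n_reg || anyDuplicated(region_labels)) {
      stop("need ", n_reg, " unique region labels")
    }
    region_of <- function(x, y) {
      idx <- findInterval(y, bnd)
      idx[idx < 1 | idx > n_reg] <- NA_integer_
      region_labels[idx]
    }
  }
  structure(list(kind = kind, params = params, region_labels = region_labels,
                 region_of = region_of),
            class = "tissue_layout")
}

#' Define a region-structured expression program
#'
#' Per-region expected molecules per cell for each gene, plus an optional
#' ambient component: genes emitted uniformly over the capture area
#' regardless of region (emulating e.g. hemoglobin transcripts from blood
#' contamination).
#'
#' @param rates numeric matrix, regions x genes, of expected molecules per
#'   cell (rows named by region, columns by gene); entries >= 0
#' @param ambient named numeric vector: expected ambient molecules per
#'   100 x 100 um of capture area at `contamination_fraction = 1`, for each
#'   ambient gene (may overlap `colnames(rates)` or extend the gene set)
#' @return an object of class `expression_program`
#' @export
expression_program <- function(rates, ambient = numeric(0)) {
  rates <- as.matrix(rates)
  if (any(rates < 0)) stop("expression rates must be nonnegative")
  if (is.null(rownames(rates)) || is.null(colnames(rates))) {
    stop("rates must have region rownames and gene colnames")
  }
  if (length(ambient) && is.null(names(ambient))) {
    stop("ambient rates must be named by gene")
  }
  structure(list(rates = rates, ambient = ambient),
            class = "expression_program")
}

#' Marker genes of an expression program
#'
#' A gene is a marker of the region where its rate is maximal, provided
#' that maximum exceeds `min_ratio` times its rate everywhere else.
#'
#' @param program an `expression_program`
#' @param min_ratio enrichment factor required (default 2)
#' @return named character vector: gene -> region
#' @export
program_markers <- function(program, min_ratio = 2) {
  rates <- program$rates
  out <- character(0)
  for (g in colnames(rates)) {
    v <- rates[, g]
    top <- which.max(v)
    rest <- max(v[-top], 0)
    if (v[top] > 0 && v[top] >= min_ratio * max(rest, .Machine$double.eps)) {
      out[g] <- rownames(rates)[top]
    }
  }
  out
}

#' Simulate a synthetic sST dataset
#'
#' Generates a spot-by-gene UMI matrix, the underlying molecule table and
#' the ground truth, with the statistical structure the benchmark analyses
#' assume:
#' \itemize{
#'   \item cells placed uniformly over the capture bounding box and
#'     labeled by the layout region at their position;
#'   \item per cell and gene, molecule counts drawn Poisson at the
#'     region's program rate;
#'   \item each molecule's capture position displaced from its cell by an
#'     isotropic Gaussian with s.d. `sigma_diff_um` (lateral diffusion);
#'   \item molecules assigned to the nearest spot center if within
#'     `spot_diameter_um / 2` (always nearest when the diameter is absent);
#'     molecules landing in dead space between spots are lost;
#'   \item each captured molecule carries `1 + Poisson(reads_per_molecule_mean - 1)`
#'     sequencing reads (duplication, the source of saturation);
#'   \item ambient genes additionally emitted uniformly over the capture
#'     area at their program rate scaled by `contamination_fraction`.
#' }
#' All randomness flows from one seeded generator in a fixed order, so a
#' given seed reproduces the dataset exactly.
#'
#' @param layout a [make_layout()] object
#' @param program an [expression_program()]
#' @param platform list with `name`, `pitch_um`, optional
#'   `spot_diameter_um`, and `capture_bbox = c(xmin, ymin, xmax, ymax)`
#' @param n_cells number of cells to place
#' @param sigma_diff_um lateral diffusion s.d. in micrometres (>= 0)
#' @param reads_per_molecule_mean mean reads per molecule (>= 1)
#' @param contamination_fraction ambient scaling in [0, 1]
#' @param seed integer seed
#' @return list with elements `counts` (a `spatial_counts`), `molecules`
#'   (a `molecule_table`), and `truth` (cell table, parameters, seed)
#' @export
simulate_dataset <- function(layout, program, platform, n_cells,
                             sigma_diff_um = 0, reads_per_molecule_mean = 1.5,
                             contamination_fraction = 0, seed) {
  stopifnot(inherits(layout, "tissue_layout"),
            inherits(program, "expression_program"))
  if (missing(seed)) stop("a seed is required for reproducibility")
  bbox <- platform$capture_bbox
  if (is.null(bbox) || length(bbox) != 4 ||
      bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("platform$capture_bbox must be c(xmin, ymin, xmax, ymax) with positive area")
  }
  pitch <- platform$pitch_um
  if (is.null(pitch) || pitch <= 0) stop("platform$pitch_um must be positive")
  if (sigma_diff_um < 0) stop("sigma_diff_um must be >= 0")
  if (reads_per_molecule_mean < 1) stop("reads_per_molecule_mean must be >= 1")
  if (contamination_fraction < 0 || contamination_fraction > 1) {
    stop("contamination_fraction must lie in [0, 1]")
  }

  # square spot grid across the bbox
  sx <- seq(bbox[1] + pitch / 2, bbox[3], by = pitch)
  sy <- seq(bbox[2] + pitch / 2, bbox[4], by = pitch)
  spot_xy <- cbind(x_um = rep(sx, times = length(sy)),
                   y_um = rep(sy, each = length(sx)))
  rownames(spot_xy) <- sprintf("spot_%05d", seq_len(nrow(spot_xy)))

  rates <- program$rates
  genes <- union(colnames(rates), names(program$ambient))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  # 1. cells
  cx <- stats::runif(n_cells, bbox[1], bbox[3])
  cy <- stats::runif(n_cells, bbox[2], bbox[4])
  creg <- layout$region_of(cx, cy)
  cells <- data.frame(cell = seq_len(n_cells), x = cx, y = cy, region = creg,
                      stringsAsFactors = FALSE)

  # 2. molecules from cells: Poisson per (cell, gene) at the region rate
  known <- creg %in% rownames(rates)
  mol_x <- numeric(0); mol_y <- numeric(0); mol_gene <- character(0)
  for (g in colnames(rates)) {
    lam <- numeric(n_cells)
    lam[known] <- rates[creg[known], g]
    n_mol <- stats::rpois(n_cells, lam)
    idx <- rep.int(seq_len(n_cells), n_mol)
    if (length(idx)) {
      mol_x <- c(mol_x, cx[idx])
      mol_y <- c(mol_y, cy[idx])
      mol_gene <- c(mol_gene, rep.int(g, length(idx)))
    }
  }

  # 3. ambient molecules, uniform over the capture area
  if (length(program$ambient) && contamination_fraction > 0) {
    area_units <- (bbox[3] - bbox[1]) * (bbox[4] - bbox[2]) / 1e4
    for (g in names(program$ambient)) {
      n_amb <- stats::rpois(1, program$ambient[[g]] * contamination_fraction *
                               area_units)
      if (n_amb > 0) {
        mol_x <- c(mol_x, stats::runif(n_amb, bbox[1], bbox[3]))
        mol_y <- c(mol_y, stats::runif(n_amb, bbox[2], bbox[4]))
        mol_gene <- c(mol_gene, rep.int(g, n_amb))
      }
    }
  }
  n_emitted <- length(mol_x)

  # 4. lateral diffusion
  if (sigma_diff_um > 0 && n_emitted > 0) {
    mol_x <- mol_x + stats::rnorm(n_emitted, 0, sigma_diff_um)
    mol_y <- mol_y + stats::rnorm(n_emitted, 0, sigma_diff_um)
  }

  # 5. capture at nearest spot center (grid lookup), optionally radius-gated
  if (n_emitted > 0) {
    ix <- pmin(pmax(round((mol_x - bbox[1] - pitch / 2) / pitch), 0),
               length(sx) - 1)
    iy <- pmin(pmax(round((mol_y - bbox[2] - pitch / 2) / pitch), 0),
               length(sy) - 1)
    spot_idx <- iy * length(sx) + ix + 1
    d2 <- (mol_x - spot_xy[spot_idx, 1])^2 + (mol_y - spot_xy[spot_idx, 2])^2
    diam <- platform$spot_diameter_um
    captured <- if (is.null(diam)) rep(TRUE, n_emitted) else d2 <= (diam / 2)^2
  } else {
    captured <- logical(0)
    spot_idx <- integer(0)
  }

  # 6. reads per captured molecule (shifted Poisson, >= 1)
  n_cap <- sum(captured)
  reads <- 1L + stats::rpois(n_cap, reads_per_molecule_mean - 1)

  mt <- molecule_table(
    spot_id = rownames(spot_xy)[spot_idx[captured]],
    gene_id = mol_gene[captured],
    molecule_id = sprintf("mol_%07d", seq_len(n_cap)),
    reads = reads
  )
  counts <- collapse_molecules(mt, spot_xy, gene_ids = genes,
                               platform = platform)
  truth <- list(cells = cells, sigma_diff_um = sigma_diff_um,
                reads_per_molecule_mean = reads_per_molecule_mean,
                contamination_fraction = contamination_fraction,
                n_emitted = n_emitted, n_captured = n_cap, seed = seed,
                layout = layout, program = program)
  list(counts = counts, molecules = mt, truth = truth)
}
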