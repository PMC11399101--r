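#' Construct a spatial count matrix
#'
#' The central container of the package: a sparse spots-by-genes matrix of
#' UMI counts together with spot center coordinates in micrometres and
#' platform metadata (array pitch, spot diameter).
#'
#' @param counts sparse or dense nonnegative integer matrix, spots in rows,
#'   genes in columns. Coerced to [Matrix::dgCMatrix-class].
#' @param coords numeric matrix or data.frame with one row per spot and two
#'   columns (x, y), in micrometres. Row order matches `counts`.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   the rownames of `counts`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the colnames of `counts`.
#' @param platform list with elements `name` (string), `pitch_um` (positive
#'   number, center-to-center spot distance) and optionally
#'   `spot_diameter_um`.
#'
#' @return An object of class `spatial_counts`: a list with elements
#'   `counts` (dgCMatrix with dimnames), `coords` (numeric matrix with
#'   columns `x_um`, `y_um` and spot ids as rownames) and `platform`.
#' @export
spatial_counts <- function(counts, coords, spot_ids = rownames(counts),
                           gene_ids = colnames(counts),
                           platform = list(name = "unknown", pitch_um = NA_real_)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(spot_ids)) stop("spot_ids are required (or rownames on counts)")
  if (is.null(gene_ids)) stop("gene_ids are required (or colnames on counts)")
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(spot_ids)) stop("duplicate spot ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(spot_ids) != nrow(counts)) stop("length(spot_ids) != nrow(counts)")
  if (length(gene_ids) != ncol(counts)) stop("length(gene_ids) != ncol(counts)")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be nonnegative integers")
  }
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  if (nrow(coords) != nrow(counts)) stop("one coordinate row per spot required")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  colnames(coords) <- c("x_um", "y_um")
  rownames(coords) <- spot_ids
  dimnames(counts) <- list(spot_ids, gene_ids)
  structure(list(counts = counts, coords = coords, platform = platform),
            class = "spatial_counts")
}

#' @export
print.spatial_counts <- function(x, ...) {
  cat(sprintf("spatial_counts: %d spots x %d genes, %s UMIs (platform: %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ","),
              x$platform$name %||% "unknown"))
  invisible(x)
}

#' @export
dim.spatial_counts <- function(x) dim(x$counts)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-spot total UMI counts
#' @param ds a `spatial_counts` object
#' @return named numeric vector of per-spot totals
#' @export
spot_totals <- function(ds) {
  stopifnot(inherits(ds, "spatial_counts"))
  Matrix::rowSums(ds$counts)
}

#' Per-gene total UMI counts
#' @param ds a `spatial_counts` object
#' @return named numeric vector of per-gene totals
#' @export
gene_totals <- function(ds) {
  stopifnot(inherits(ds, "spatial_counts"))
  Matrix::colSums(ds$counts)
}

subset_spots <- function(ds, keep) {
  # explicit ids: sparse subsetting drops dimnames on zero-row results
  spatial_counts(ds$counts[keep, , drop = FALSE],
                 ds$coords[keep, , drop = FALSE],
                 spot_ids = rownames(ds$coords)[keep],
                 gene_ids = colnames(ds$counts),
                 platform = ds$platform)
}

#' Construct a molecule table
#'
#' Long-form molecule-level records: one row per captured molecule (UMI)
#' carrying its read multiplicity. This is the substrate for read-level
#' downsampling; collapsing molecules per spot and gene reproduces the UMI
#' count matrix.
#'
#' @param spot_id,gene_id,molecule_id character vectors, one entry per
#'   molecule; `(spot_id, gene_id, molecule_id)` triples must be unique.
#' @param reads integer vector of reads per molecule, all >= 1.
#' @return A data.frame of class `molecule_table` with columns `spot_id`,
#'   `gene_id`, `molecule_id`, `reads`.
#' @export
molecule_table <- function(spot_id, gene_id, molecule_id, reads) {
  reads <- as.integer(reads)
  if (length(reads) && any(reads < 1L)) stop("every molecule needs >= 1 read")
  mt <- data.frame(spot_id = as.character(spot_id),
                   gene_id = as.character(gene_id),
                   molecule_id = as.character(molecule_id),
                   reads = reads, stringsAsFactors = FALSE)
  key <- paste(mt$spot_id, mt$gene_id, mt$molecule_id, sep = "\r")
  if (anyDuplicated(key)) stop("(spot_id, gene_id, molecule_id) must be unique")
  class(mt) <- c("molecule_table", "data.frame")
  mt
}

#' Total sequenced reads in a molecule table
#' @param mt a `molecule_table`
#' @return integer total read count
#' @export
total_reads <- function(mt) {
  stopifnot(inherits(mt, "molecule_table"))
  sum(mt$reads)
}

#' Collapse a molecule table to a spatial count matrix
#'
#' Counts distinct molecules per spot and gene. Spot coordinates must be
#' supplied (molecule records carry no geometry).
#'
#' @param mt a `molecule_table`
#' @param coords numeric matrix of spot coordinates with spot ids as
#'   rownames; must cover every spot present in `mt`.
#' @param gene_ids optional gene universe (columns of the result); defaults
#'   to the genes present in `mt`.
#' @param platform platform metadata list, as in [spatial_counts()].
#' @return a `spatial_counts` object whose entries are molecule counts
#' @export
collapse_molecules <- function(mt, coords, gene_ids = NULL,
                               platform = list(name = "unknown", pitch_um = NA_real_)) {
  stopifnot(inherits(mt, "molecule_table"))
  spot_ids <- rownames(coords)
  if (is.null(spot_ids)) stop("coords must have spot ids as rownames")
  if (is.null(gene_ids)) gene_ids <- sort(unique(mt$gene_id))
  missing_spots <- setdiff(mt$spot_id, spot_ids)
  if (length(missing_spots)) {
    stop("no coordinates for spot(s): ", paste(utils::head(missing_spots, 5), collapse = ", "))
  }
  i <- match(mt$spot_id, spot_ids)
  j <- match(mt$gene_id, gene_ids)
  if (anyNA(j)) stop("molecule table contains genes outside gene_ids")
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(spot_ids), length(gene_ids)),
                                 dimnames = list(spot_ids, gene_ids))
  spatial_counts(counts, coords, platform = platform)
}
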