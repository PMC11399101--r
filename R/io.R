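#' Read a spatial dataset from Matrix Market files
#'
#' Reads the standard triplet of files exported by sST pipelines — a Matrix
#' Market coordinate matrix, barcodes and features lists — plus a positions
#' table mapping every barcode to micrometre coordinates. Indices on disk
#' are 1-based, as the Matrix Market format prescribes. The matrix may be
#' stored either spots-by-genes or genes-by-spots; orientation is resolved
#' against the barcode/feature counts.
#'
#' @param matrix_path path to the `.mtx` file (coordinate integer format)
#' @param barcodes_path path to barcodes file, one spot barcode per line
#' @param features_path path to features file, one gene id per line
#' @param positions_path path to a CSV with header `barcode,x_um,y_um`
#' @param platform platform metadata list, see [spatial_counts()]
#' @return a `spatial_counts` object
#' @export
read_spatial_dataset <- function(matrix_path, barcodes_path, features_path,
                                 positions_path,
                                 platform = list(name = "unknown", pitch_um = NA_real_)) {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) stop("malformed Matrix Market file '",
                                         matrix_path, "': ", conditionMessage(e)))
  barcodes <- readLines(barcodes_path)
  features <- readLines(features_path)
  barcodes <- barcodes[nzchar(barcodes)]
  features <- features[nzchar(features)]
  if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    # spots x genes already
  } else if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)
  } else {
    stop("matrix dimensions ", nrow(m), "x", ncol(m),
         " match neither barcodes (", length(barcodes),
         ") x features (", length(features), ") orientation")
  }
  pos <- utils::read.csv(positions_path, stringsAsFactors = FALSE)
  need <- c("barcode", "x_um", "y_um")
  if (!all(need %in% names(pos))) {
    stop("positions file must have header 'barcode,x_um,y_um'")
  }
  idx <- match(barcodes, pos$barcode)
  if (anyNA(idx)) {
    missing <- barcodes[is.na(idx)]
    stop("no position for barcode(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  coords <- cbind(x_um = pos$x_um[idx], y_um = pos$y_um[idx])
  rownames(coords) <- barcodes
  spatial_counts(m, coords, spot_ids = barcodes, gene_ids = features,
                 platform = platform)
}

#' Write a spatial dataset to Matrix Market files
#'
#' Inverse of [read_spatial_dataset()]; writes `matrix.mtx`,
#' `barcodes.tsv`, `features.tsv` and `positions.csv` under `dir`.
#'
#' @param ds a `spatial_counts` object
#' @param dir output directory (created if absent)
#' @return invisibly, the directory path
#' @export
write_spatial_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spatial_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(ds$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(ds$counts), file.path(dir, "features.tsv"))
  pos <- data.frame(barcode = rownames(ds$coords),
                    x_um = ds$coords[, "x_um"], y_um = ds$coords[, "y_um"])
  utils::write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read or write a molecule table as TSV
#'
#' Plain TSV with header `spot_id gene_id molecule_id reads`.
#'
#' @param path file path
#' @return for the reader, a `molecule_table`
#' @export
read_molecule_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spot_id", "gene_id", "molecule_id", "reads")
  if (!all(need %in% names(df))) {
    stop("molecule table must have columns: ", paste(need, collapse = ", "))
  }
  molecule_table(df$spot_id, df$gene_id, df$molecule_id, df$reads)
}

#' @rdname read_molecule_table
#' @param mt a `molecule_table`
#' @export
write_molecule_table <- function(mt, path) {
  stopifnot(inherits(mt, "molecule_table"))
  utils::write.table(as.data.frame(mt), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Region of interest polygons
#'
#' A region of interest (ROI) is a simple polygon in micrometre
#' coordinates, typically drawn around a histological structure. Stored on
#' disk as JSON: `{"name": ..., "polygon": [[x, y], ...]}`.
#'
#' @param polygon numeric matrix or list of >= 3 (x, y) vertices; the
#'   polygon is implicitly closed.
#' @param name region name
#' @return an object of class `roi`
#' @export
roi <- function(polygon, name = "roi") {
  if (is.list(polygon)) polygon <- do.call(rbind, lapply(polygon, as.numeric))
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  if (nrow(polygon) < 3) stop("a polygon needs at least 3 vertices")
  if (!all(is.finite(polygon))) stop("polygon vertices must be finite")
  if (polygon_self_intersects(polygon)) stop("polygon is self-intersecting")
  if (polygon_area(polygon) <= 0) stop("degenerate polygon: zero area")
  structure(list(polygon = polygon[, 1:2, drop = FALSE], name = name),
            class = "roi")
}

#' @rdname roi
#' @param path path to a JSON ROI file
#' @export
read_roi <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi(obj$polygon, name = obj$name %||% "roi")
}

#' @rdname roi
#' @param x an `roi` object to serialize
#' @export
write_roi <- function(x, path) {
  stopifnot(inherits(x, "roi"))
  jsonlite::write_json(list(name = x$name, polygon = unname(x$polygon)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Shoelace area (absolute value).
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

# Proper-crossing test between non-adjacent edges; shared endpoints of
# adjacent edges are not intersections.
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n <= 3) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (a in seq_len(n - 2)) {
    bs <- (a + 2):n
    bs <- bs[!(a == 1 & bs == n)]  # skip adjacent wrap-around pair
    for (b in bs) {
      p1 <- seg[a, 1:2]; p2 <- seg[a, 3:4]
      p3 <- seg[b, 1:2]; p4 <- seg[b, 3:4]
      d1 <- cross(p4[1] - p3[1], p4[2] - p3[2], p1[1] - p3[1], p1[2] - p3[2])
      d2 <- cross(p4[1] - p3[1], p4[2] - p3[2], p2[1] - p3[1], p2[2] - p3[2])
      d3 <- cross(p2[1] - p1[1], p2[2] - p1[2], p3[1] - p1[1], p3[2] - p1[2])
      d4 <- cross(p2[1] - p1[1], p2[2] - p1[2], p4[1] - p1[1], p4[2] - p1[2])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read a gene annotation table
#'
#' CSV with header `gene,biotype,length_bp,gc_fraction`. Used by the
#' capture-bias analyses to relate flagged genes to GC content, length and
#' biotype.
#'
#' @param path CSV path
#' @return data.frame with one row per gene
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene", "biotype", "length_bp", "gc_fraction")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  gene_annotation(ann)
}

#' @rdname read_gene_annotation
#' @param ann data.frame with columns `gene`, `biotype`, `length_bp`,
#'   `gc_fraction`
#' @export
gene_annotation <- function(ann) {
  if (any(ann$gc_fraction < 0 | ann$gc_fraction > 1, na.rm = TRUE)) {
    stop("gc_fraction must lie in [0, 1]")
  }
  if (any(ann$length_bp < 1, na.rm = TRUE)) stop("length_bp must be >= 1")
  if (anyDuplicated(ann$gene)) stop("duplicate gene in annotation")
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}
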