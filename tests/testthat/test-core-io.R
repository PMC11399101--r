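test_that("Matrix Market round trip preserves counts and coordinates", {
  ds <- random_counts(12, 7, seed = 11)
  dir <- withr::local_tempdir()
  write_spatial_dataset(ds, dir)
  back <- read_spatial_dataset(file.path(dir, "matrix.mtx"),
                               file.path(dir, "barcodes.tsv"),
                               file.path(dir, "features.tsv"),
                               file.path(dir, "positions.csv"))
  expect_identical(as.matrix(back$counts), as.matrix(ds$counts))
  expect_equal(back$coords, ds$coords, tolerance = 1e-12)
})

test_that("reader transcribes triplets and rejects missing positions", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 3", "1 1 4", "2 2 1", "3 1 2"),
             file.path(dir, "m.mtx"))
  writeLines(c("S1", "S2", "S3"), file.path(dir, "b.tsv"))
  writeLines(c("gA", "gB"), file.path(dir, "f.tsv"))
  writeLines(c("barcode,x_um,y_um", "S1,0,0", "S2,10,0", "S3,20,0"),
             file.path(dir, "p.csv"))
  ds <- read_spatial_dataset(file.path(dir, "m.mtx"), file.path(dir, "b.tsv"),
                             file.path(dir, "f.tsv"), file.path(dir, "p.csv"))
  expect_equal(unname(gene_totals(ds)), c(6, 1))

  # empty entry list, valid header -> all-zero matrix
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "3 2 0"),
             file.path(dir, "empty.mtx"))
  ds0 <- read_spatial_dataset(file.path(dir, "empty.mtx"),
                              file.path(dir, "b.tsv"), file.path(dir, "f.tsv"),
                              file.path(dir, "p.csv"))
  expect_equal(sum(ds0$counts), 0)
  expect_equal(dim(ds0), c(3L, 2L))

  # missing position for S3 -> error naming the barcode
  writeLines(c("barcode,x_um,y_um", "S1,0,0", "S2,10,0"),
             file.path(dir, "p2.csv"))
  expect_error(
    read_spatial_dataset(file.path(dir, "m.mtx"), file.path(dir, "b.tsv"),
                         file.path(dir, "f.tsv"), file.path(dir, "p2.csv")),
    "S3")
})

test_that("bin_spots sums counts on a half-open grid and conserves totals", {
  ds <- toy_counts(matrix(c(2, 5), ncol = 1), rbind(c(1, 1), c(3, 3)))
  b <- bin_spots(ds, 10)
  expect_equal(nrow(b$counts), 1)
  expect_equal(unname(b$coords[1, ]), c(5, 5))
  expect_equal(sum(b$counts), 7)

  # half-open convention: x = 10 falls in [10, 20)
  ds2 <- toy_counts(matrix(c(1, 1), ncol = 1), rbind(c(9.99, 0), c(10, 0)))
  b2 <- bin_spots(ds2, 10)
  expect_equal(nrow(b2$counts), 2)
  expect_setequal(b2$coords[, "x_um"], c(5, 15))

  # conservation on random fixtures for arbitrary bin sizes
  for (bin in c(0.7, 3, 10, 500)) {
    dsr <- random_counts(40, 9, seed = 21)
    expect_identical(sum(bin_spots(dsr, bin)$counts), sum(dsr$counts))
  }
  expect_error(bin_spots(ds, 0), "positive")
})

test_that("select_roi keeps centers inside the polygon, edge inclusive", {
  sq <- roi(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), "sq")
  ds <- toy_counts(matrix(1:3, ncol = 1),
                   rbind(c(5, 5), c(15, 5), c(10, 5)))
  sel <- select_roi(ds, sq)
  expect_setequal(rownames(sel$counts), c("S1", "S3"))  # S3 on the edge
  # idempotent
  expect_identical(select_roi(sel, sq)$counts, sel$counts)
  # polygon containing no centers -> empty, no error
  far <- roi(rbind(c(100, 100), c(110, 100), c(110, 110)), "far")
  expect_equal(nrow(select_roi(ds, far)$counts), 0)
  expect_error(roi(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("quality filter uses 30% of the type-7 first quartile", {
  mk <- function(totals) {
    toy_counts(matrix(totals, ncol = 1), cbind(seq_along(totals), 0))
  }
  expect_equal(nrow(filter_low_quality(mk(c(100, 200, 300, 400)))$counts), 4)
  kept <- filter_low_quality(mk(c(10, 200, 300, 400)))
  expect_equal(nrow(kept$counts), 3)     # Q1 = 152.5, threshold 45.75
  expect_false("S1" %in% rownames(kept$counts))
  expect_equal(nrow(filter_low_quality(mk(rep(7, 6)))$counts), 6)
  expect_error(filter_low_quality(mk(c(1, 2, 3))), ">= 4")
  # never removes the maximum-total spot
  for (s in 1:5) {
    ds <- random_counts(25, 4, seed = 100 + s)
    kept <- filter_low_quality(ds)
    expect_true(names(which.max(spot_totals(ds))) %in% rownames(kept$counts))
  }
})

test_that("median normalization scales every spot to the median total", {
  counts <- matrix(c(5, 5, 10, 10, 15, 15), nrow = 3, byrow = TRUE)
  ds <- toy_counts(counts, cbind(1:3, 0))
  norm <- normalize_median(ds)   # totals 10, 20, 30; median 20
  expect_equal(norm["S1", "g1"], 10)  # 5 / 10 * 20
  expect_equal(unname(Matrix::rowSums(norm)), rep(20, 3))
  # equal totals -> identity
  dse <- toy_counts(matrix(c(3, 7, 6, 4), 2, byrow = TRUE), cbind(1:2, 0))
  expect_equal(as.matrix(normalize_median(dse)), as.matrix(dse$counts),
               ignore_attr = TRUE)
  dz <- toy_counts(matrix(c(0, 0, 1, 2), 2, byrow = TRUE), cbind(1:2, 0))
  expect_error(normalize_median(dz), "S1")
})

test_that("molecule table validates reads and collapses to counts exactly", {
  expect_error(toy_molecules(c(1, 0)), ">= 1")
  mt <- molecule_table(c("S1", "S1", "S2"), c("g1", "g1", "g2"),
                       c("m1", "m2", "m3"), c(3, 1, 2))
  coords <- rbind(S1 = c(0, 0), S2 = c(10, 0))
  ds <- collapse_molecules(mt, coords)
  expect_equal(as.matrix(ds$counts),
               matrix(c(2, 0, 0, 1), 2, dimnames = list(c("S1", "S2"),
                                                        c("g1", "g2"))))
  expect_error(
    molecule_table(c("S1", "S1"), c("g1", "g1"), c("m1", "m1"), c(1, 1)),
    "unique")
  # TSV round trip
  path <- withr::local_tempfile()
  write_molecule_table(mt, path)
  expect_identical(read_molecule_table(path), mt)
})

test_that("ROI JSON round trip and polygon validation", {
  r <- roi(rbind(c(0, 0), c(20, 0), c(20, 30), c(0, 30)), "eye")
  path <- withr::local_tempfile(fileext = ".json")
  write_roi(r, path)
  back <- read_roi(path)
  expect_equal(back$polygon, r$polygon, ignore_attr = TRUE)
  expect_identical(back$name, "eye")
  expect_error(roi(rbind(c(0, 0), c(1, 0))), "3 vertices")
  # bow-tie self-intersection
  expect_error(roi(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersecting")
})
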