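# Shared fixture builders: everything is generated in code, no data files.

# Small spatial_counts with explicit coordinates and counts.
toy_counts <- function(counts, coords, pitch = 10) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  }
  spatial_counts(counts, coords,
                 platform = list(name = "toy", pitch_um = pitch))
}

# Molecule table with given per-molecule read counts, all on one spot/gene
# unless vectors are supplied.
toy_molecules <- function(reads, spot = "S1", gene = "g1") {
  n <- length(reads)
  molecule_table(rep_len(spot, n), rep_len(gene, n),
                 paste0("m", seq_len(n)), reads)
}

# Random sparse fixture on an integer grid, seeded.
random_counts <- function(n_spots, n_genes, seed, lambda = 2, pitch = 10) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_spots * n_genes, lambda), n_spots, n_genes)
    coords <- cbind(runif(n_spots, 0, 500), runif(n_spots, 0, 500))
    toy_counts(counts, coords, pitch = pitch)
  })
}

# Hand-built intensity profile.
toy_profile <- function(values, bin_um = 10) {
  sstbench:::intensity_profile(values, bin_um)
}

# Brute-force ECA oracle: literal double loop over predicted clusters and
# reference classes, independent of contingency().
oracle_eca <- function(pred, ref) {
  shared <- intersect(names(pred), names(ref))
  pred <- pred[shared]; ref <- ref[shared]
  clusters <- unique(pred)
  total <- 0
  for (cl in clusters) {
    in_cl <- names(pred)[pred == cl]
    h <- 0
    for (k in unique(ref)) {
      p <- sum(ref[in_cl] == k) / length(in_cl)
      if (p > 0) h <- h - p * log(p)
    }
    total <- total + h
  }
  total / length(clusters)
}

# Layered boundary-marker scenario used by the diffusion recovery tests:
# a thin high-expression band, marker zero elsewhere.
band_scenario <- function() {
  layout <- make_layout("layers", list(boundaries = c(0, 100, 110, 300)),
                        region_labels = c("below", "band", "above"))
  rates <- matrix(c(0, 30, 0,      # Mk: band only
                    0.5, 0.5, 0.5),# Bg: uniform background
                  nrow = 3, dimnames = list(c("below", "band", "above"),
                                            c("Mk", "Bg")))
  program <- expression_program(rates)
  platform <- list(name = "sim", pitch_um = 10, spot_diameter_um = 10,
                   capture_bbox = c(0, 0, 200, 300))
  list(layout = layout, program = program, platform = platform)
}

# Median LWHM of the band marker over three parallel strips.
band_median_lwhm <- function(sigma, seed, n_cells = 4000) {
  sc <- band_scenario()
  sim <- simulate_dataset(sc$layout, sc$program, sc$platform,
                          n_cells = n_cells, sigma_diff_um = sigma,
                          reads_per_molecule_mean = 1.5,
                          contamination_fraction = 0, seed = seed)
  strips <- list(strip(c(50, 0), c(0, 1), 300),
                 strip(c(100, 0), c(0, 1), 300),
                 strip(c(150, 0), c(0, 1), 300))
  vals <- vapply(strips, function(s) {
    lwhm(strip_profile(sim$counts, "Mk", s))
  }, numeric(1))
  median(vals, na.rm = TRUE)
}
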