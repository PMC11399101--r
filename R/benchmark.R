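#' Canonical two-platform demo scenario
#'
#' A ready-made benchmark configuration: an embryonic-eye-like ring layout
#' (lens enveloped by neural retina and a melanocyte ring) sampled by two
#' synthetic platforms that differ in spot pitch, capture efficiency,
#' lateral diffusion and blood-like ambient contamination. All downstream
#' stages of [run_full_benchmark()] run on this scenario.
#'
#' @param out_dir directory the benchmark writes into
#' @param seed integer master seed; all stage seeds derive from it
#' @return a configuration list accepted by [run_full_benchmark()]
#' @export
demo_config <- function(out_dir, seed = 1L) {
  layout <- make_layout("eye_rings",
                        list(center = c(150, 150), radii = c(50, 100, 120)),
                        region_labels = c("lens", "pNR", "melanocyte", "outside"))
  regions <- c("lens", "pNR", "melanocyte", "outside")
  genes <- c("Vit", "Crybb3", "Aldh1a1", "Pmel", sprintf("Bg%03d", 1:30))
  rates <- matrix(0.4, nrow = length(regions), ncol = length(genes),
                  dimnames = list(regions, genes))
  rates["lens", c("Vit", "Crybb3")] <- c(8, 6)
  rates[c("pNR", "melanocyte", "outside"), c("Vit", "Crybb3")] <- 0
  rates["pNR", "Aldh1a1"] <- 5
  rates[c("lens", "melanocyte", "outside"), "Aldh1a1"] <- 0
  rates["melanocyte", "Pmel"] <- 6
  rates[c("lens", "pNR", "outside"), "Pmel"] <- 0
  program <- expression_program(rates, ambient = c(`Hba-a1` = 40))
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    layout = layout,
    program = program,
    platforms = list(
      alpha = list(name = "alpha", pitch_um = 10, spot_diameter_um = 10,
                   capture_bbox = c(0, 0, 300, 300), n_cells = 2000,
                   sigma_diff_um = 2, reads_per_molecule_mean = 2.5,
                   contamination_fraction = 0.3),
      beta = list(name = "beta", pitch_um = 10, spot_diameter_um = 7,
                  capture_bbox = c(0, 0, 300, 300), n_cells = 2000,
                  sigma_diff_um = 12, reads_per_molecule_mean = 3.5,
                  contamination_fraction = 0.7)
    ),
    roi = roi(rbind(c(90, 90), c(210, 90), c(210, 210), c(90, 210)),
              name = "eye"),
    windows = window_set(x0 = c(100, 150, 125, 100, 150),
                         y0 = c(100, 100, 125, 150, 150)),
    window_genes = c("Vit", "Crybb3"),
    # radial strips crossing the melanocyte ring from outside inward,
    # so the profile peaks at the ring and decays leftward
    strips = list(
      strip(anchor = c(300, 150), axis = c(-1, 0), length_um = 200),
      strip(anchor = c(150, 300), axis = c(0, -1), length_um = 200),
      strip(anchor = c(0, 150), axis = c(1, 0), length_um = 200)
    ),
    diffusion_gene = "Pmel",
    proportions = c(0.1, 0.25, 0.5, 0.75, 1),
    marker_groups = c(group1 = "lens", group2 = "pNR"),
    ambient_gene = "Hba-a1",
    n_clusters = 3
  )
}

#' Run the full benchmark pipeline on a configuration
#'
#' Executes every analysis stage end to end on seeded synthetic data:
#' simulation, saturation curves, ROI/window sensitivity (at common
#' depth), strip-profile diffusion summaries with LWHM, clustering
#' concordance under downsampling (ECA/ECP against the full-data
#' labeling, using a k-means demo labeler), marker detection with depth
#' curves and cross-platform intersection, pairwise capture-bias flags
#' and the ambient-contamination fraction. Writes per-stage CSV files and
#' a machine-readable `summary.json` under `config$out_dir`; a rerun with
#' the same configuration reproduces every file byte for byte.
#'
#' @param config a configuration list, e.g. from [demo_config()]
#' @return invisibly, the summary list written to `summary.json`
#' @export
run_full_benchmark <- function(config) {
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir is required")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("benchmark stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sims <- stage("simulate", {
    sims <- lapply(seq_along(config$platforms), function(i) {
      pf <- config$platforms[[i]]
      simulate_dataset(config$layout, config$program, pf,
                       n_cells = pf$n_cells,
                       sigma_diff_um = pf$sigma_diff_um,
                       reads_per_molecule_mean = pf$reads_per_molecule_mean,
                       contamination_fraction = pf$contamination_fraction,
                       seed = seed + i)
    })
    names(sims) <- names(config$platforms)
    for (nm in names(sims)) {
      dir <- file.path(out, nm)
      write_spatial_dataset(sims[[nm]]$counts, dir)
      write_molecule_table(sims[[nm]]$molecules,
                           file.path(dir, "molecules.tsv"))
      tr <- sims[[nm]]$truth
      jsonlite::write_json(list(sigma_diff_um = tr$sigma_diff_um,
                                reads_per_molecule_mean = tr$reads_per_molecule_mean,
                                contamination_fraction = tr$contamination_fraction,
                                n_emitted = tr$n_emitted,
                                n_captured = tr$n_captured, seed = tr$seed),
                           file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    sims
  })
  datasets <- lapply(sims, `[[`, "counts")
  molecules <- lapply(sims, `[[`, "molecules")

  stage("saturation", {
    sat <- do.call(rbind, lapply(names(molecules), function(nm) {
      cbind(platform = nm,
            saturation_curve(molecules[[nm]], config$proportions,
                             n_rep = 5L, seed = seed + 100L))
    }))
    utils::write.csv(sat, file.path(out, "saturation.csv"), row.names = FALSE,
                     quote = FALSE)
  })

  sens <- stage("sensitivity", {
    roi_ds <- lapply(datasets, select_roi, region = config$roi)
    sens <- compare_platforms_sensitivity(roi_ds, config$windows,
                                          config$window_genes,
                                          molecules = molecules,
                                          common_depth = TRUE,
                                          seed = seed + 200L)
    utils::write.csv(sens, file.path(out, "sensitivity.csv"),
                     row.names = FALSE, quote = FALSE)
    sens
  })

  diff_sum <- stage("diffusion", {
    strips <- stats::setNames(rep(list(config$strips), length(datasets)),
                              names(datasets))
    ds <- diffusion_summary(datasets, strips, config$diffusion_gene)
    utils::write.csv(ds$per_modality, file.path(out, "lwhm_per_modality.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(ds$summary, file.path(out, "lwhm_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    ds
  })

  conc <- stage("cluster_eval", {
    conc <- do.call(rbind, lapply(names(datasets), function(nm) {
      full <- demo_cluster_labels(datasets[[nm]], config$n_clusters,
                                  seed = seed + 300L)
      labs <- lapply(config$proportions, function(p) {
        target <- floor(p * total_reads(molecules[[nm]]) + 0.5)
        sub <- downsample_reads(molecules[[nm]], target,
                                seed = seed + 300L + round(1000 * p))
        dds <- collapse_molecules(sub, datasets[[nm]]$coords,
                                  gene_ids = colnames(datasets[[nm]]$counts))
        demo_cluster_labels(dds, config$n_clusters, seed = seed + 301L)
      })
      names(labs) <- config$proportions
      cbind(platform = nm, downsample_concordance(full, labs))
    }))
    utils::write.csv(conc, file.path(out, "cluster_concordance.csv"),
                     row.names = FALSE, quote = FALSE)
    conc
  })

  markers_out <- stage("markers", {
    grp <- function(ds) {
      reg <- config$layout$region_of(ds$coords[, "x_um"], ds$coords[, "y_um"])
      totals <- spot_totals(ds)
      list(g1 = rownames(ds$coords)[reg == config$marker_groups[["group1"]] & totals > 0],
           g2 = rownames(ds$coords)[reg == config$marker_groups[["group2"]] & totals > 0])
    }
    sets <- list()
    for (nm in names(datasets)) {
      ds <- datasets[[nm]]
      g <- grp(ds)
      norm <- normalize_median(subset_spots(ds, spot_totals(ds) > 0))
      tab <- wilcoxon_markers(norm, g$g1, g$g2)
      utils::write.csv(tab, file.path(out, paste0("markers_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
      sets[[nm]] <- filter_markers(tab)
    }
    inter <- marker_intersection(sets)
    utils::write.csv(inter$membership, file.path(out, "marker_intersection.csv"),
                     row.names = FALSE, quote = FALSE)
    ds1 <- datasets[[1]]
    g <- grp(ds1)
    coords1 <- stats::setNames(list(ds1$coords), names(datasets)[1])
    depth_curve <- marker_depth_curve(molecules[1], coords1, g$g1, g$g2,
                                      proportions = config$proportions,
                                      seed = seed + 400L)
    utils::write.csv(depth_curve, file.path(out, "marker_depth_curve.csv"),
                     row.names = FALSE, quote = FALSE)
    list(sets = sets, tiers = inter$tier_counts)
  })

  bias_out <- stage("bias", {
    totals <- lapply(datasets, gene_totals)
    cmp <- pairwise_gene_compare(totals[[1]], totals[[2]])
    utils::write.csv(cmp$table, file.path(out, "bias_pairwise.csv"),
                     row.names = FALSE, quote = FALSE)
    contam <- vapply(datasets, contamination_fraction,
                     numeric(1), gene = config$ambient_gene)
    list(flagged = cmp$flagged, contamination = contam)
  })

  summary <- list(
    seed = seed,
    platforms = names(datasets),
    total_umis = lapply(datasets, function(d) sum(d$counts)),
    sensitivity_rank = stats::setNames(as.list(sens$rank), sens$platform),
    median_lwhm = stats::setNames(as.list(diff_sum$summary$median_lwhm),
                                  diff_sum$summary$platform),
    eca_at_full = stats::setNames(
      as.list(conc$eca[conc$proportion == 1]),
      conc$platform[conc$proportion == 1]),
    n_markers = lapply(markers_out$sets, length),
    marker_tiers = as.list(markers_out$tiers),
    bias_flagged = bias_out$flagged,
    contamination_fraction = as.list(bias_out$contamination)
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Demo clustering labeler (k-means)
#'
#' A convenience labeler so the clustering-evaluation stage can run
#' without an external clustering tool: k-means (fixed seed, 10 restarts)
#' on log1p of median-normalized counts. Not part of the evaluated
#' surface — real use cases feed labels from their own clustering runs.
#'
#' @param ds a `spatial_counts` object
#' @param k number of clusters
#' @param seed integer seed
#' @return named character vector: spot id -> cluster label
#' @export
demo_cluster_labels <- function(ds, k, seed = 1L) {
  ds <- subset_spots(ds, spot_totals(ds) > 0)
  norm <- normalize_median(ds)
  x <- log1p(as.matrix(norm))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 10, iter.max = 50)
  stats::setNames(paste0("k", km$cluster), rownames(x))
}
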