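test_that("strip profiles bin projected spots, half-open along the axis", {
  ds <- toy_counts(matrix(c(2, 7), ncol = 1), rbind(c(5, 0), c(25, 0)))
  s <- strip(anchor = c(0, 0), axis = c(1, 0), length_um = 30, width_um = 50)
  p <- strip_profile(ds, "g1", s)
  expect_equal(p$values, c(2, 0, 7))
  expect_equal(p$peak_index, 3L)
  expect_equal(p$bin_centers, c(5, 15, 25))
  # no spots in the strip -> all-zero profile, peak flagged undefined
  s_far <- strip(anchor = c(0, 500), axis = c(1, 0), length_um = 30)
  p0 <- strip_profile(ds, "g1", s_far)
  expect_equal(sum(p0$values), 0)
  expect_true(is.na(p0$peak_index))
  expect_error(strip_profile(ds, character(0), s), "at least one gene")
})

test_that("strip profiles are invariant under joint rotation", {
  ds <- random_counts(80, 3, seed = 41)
  s <- strip(anchor = c(100, 100), axis = c(1, 0), length_um = 200,
             width_um = 60)
  base <- strip_profile(ds, colnames(ds$counts), s)$values
  th <- 0.6
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot_xy <- ds$coords %*% t(Rm)
  ds_rot <- spatial_counts(ds$counts, rot_xy, platform = ds$platform)
  anchor_rot <- as.numeric(Rm %*% c(100, 100))
  axis_rot <- as.numeric(Rm %*% c(1, 0))
  s_rot <- strip(anchor = anchor_rot, axis = axis_rot, length_um = 200,
                 width_um = 60)
  expect_equal(strip_profile(ds_rot, colnames(ds$counts), s_rot)$values, base,
               tolerance = 1e-10)
})

test_that("peak alignment shifts, truncates to overlap, and filters", {
  p1 <- toy_profile(c(0, 40, 0, 0))
  p2 <- toy_profile(c(0, 0, 40, 0))
  avg <- align_and_average(list(p1, p2))
  # peaks at indices 2 and 3; overlap spans one bin left, one right
  expect_equal(avg$values, c(0, 40, 0))
  expect_equal(avg$peak_index, 2L)
  # averaging a profile with itself is the identity
  same <- align_and_average(list(p1, p1))
  expect_equal(same$values, p1$values)
  # zero-total profile dropped by the insufficient-counts filter
  mixed <- align_and_average(list(p1, toy_profile(c(0, 0, 0, 0))))
  expect_equal(mixed$values, p1$values)
  expect_error(align_and_average(list(toy_profile(c(1, 0, 0, 0)))),
               "filtered out")
})

test_that("AUC normalization scales to unit area and is scale invariant", {
  p <- toy_profile(c(1, 1, 2))
  n <- normalize_auc(p)
  expect_equal(n$values, c(0.025, 0.025, 0.05))
  expect_equal(sum(n$values) * n$bin_um, 1, tolerance = 1e-9)
  expect_equal(normalize_auc(n)$values, n$values)
  expect_equal(normalize_auc(toy_profile(c(3, 3, 6)))$values, n$values)
  expect_error(normalize_auc(toy_profile(c(0, 0))), "all-zero")
})

test_that("LWHM: triangle, Gaussian, and undefined cases", {
  tri <- toy_profile(c(0, 1, 2, 3, 4, 3, 2, 1, 0))
  expect_equal(lwhm(tri), 20)
  # scale invariance and invariance under AUC normalization
  expect_equal(lwhm(toy_profile(7 * c(0, 1, 2, 3, 4, 3, 2, 1, 0))), 20)
  expect_equal(lwhm(normalize_auc(tri)), 20)
  # finely binned Gaussian: LWHM ~ sigma * sqrt(2 ln 2)
  centers <- seq(0.5, 199.5, by = 1)
  g <- toy_profile(dnorm(centers, mean = 120, sd = 10), bin_um = 1)
  expect_lt(abs(lwhm(g) - 10 * sqrt(2 * log(2))), 0.5)
  # flat to the left edge or all-zero -> undefined, not an error
  expect_true(is.na(lwhm(toy_profile(c(4, 4, 4)))))
  expect_true(is.na(lwhm(toy_profile(c(0, 0, 0)))))
  expect_true(is.na(lwhm(toy_profile(c(5, 1, 0)))))  # peak at left edge
})

test_that("diffusion summary ranks platforms by median LWHM", {
  sharp <- toy_profile(c(0, 0, 1, 10, 1, 0))
  wide <- toy_profile(c(1, 4, 7, 10, 7, 4))
  mk_ds <- function(values) {
    # one spot per bin center along x at y = 0
    toy_counts(matrix(values, ncol = 1),
               cbind((seq_along(values) - 0.5) * 10, 0))
  }
  strips <- list(strip(c(0, 0), c(1, 0), 60))
  datasets <- list(tight = mk_ds(sharp$values), smeared = mk_ds(wide$values))
  res <- diffusion_summary(datasets,
                           list(tight = strips, smeared = strips), "g1")
  summ <- res$summary
  expect_equal(summ$rank[summ$platform == "tight"], 1L)
  expect_lt(summ$median_lwhm[summ$platform == "tight"],
            summ$median_lwhm[summ$platform == "smeared"])
  # a platform whose modalities are all undefined is excluded with a warning
  datasets$flat <- mk_ds(c(8, 8, 8, 8, 8, 8))
  expect_warning(
    res2 <- diffusion_summary(datasets,
                              list(tight = strips, smeared = strips,
                                   flat = strips), "g1"),
    "flat")
  expect_true(is.na(res2$summary$rank[res2$summary$platform == "flat"]))
})

test_that("dispersion clusters report centroid-distance variance", {
  # square corners: equal centroid distances -> variance 0
  sq <- toy_counts(matrix(1, 4, 1),
                   rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))
  res <- dispersion_clusters(sq, "g1", eps_um = 10, min_pts = 3)
  expect_equal(nrow(res), 1)
  expect_equal(res$distance_variance, 0)
  expect_equal(res$n_spots, 4)
  # collinear spots: distances to centroid (2,0) are 2, 1, 3 -> var 1
  col3 <- toy_counts(matrix(c(2, 4, 6), ncol = 1),
                     rbind(c(0, 0), c(1, 0), c(5, 0)))
  res3 <- dispersion_clusters(col3, "g1", eps_um = 10, min_pts = 2)
  expect_equal(res3$distance_variance, 1)
  expect_equal(res3$mean_count, 4)
  # single expressing spot with min_pts 1 -> singleton cluster, variance 0
  one <- toy_counts(matrix(c(3, 0), ncol = 1), rbind(c(0, 0), c(50, 50)))
  res1 <- dispersion_clusters(one, "g1", eps_um = 5, min_pts = 1)
  expect_equal(res1$n_spots, 1)
  expect_equal(res1$distance_variance, 0)
  # no expressing spots -> empty result, not an error
  zero <- toy_counts(matrix(0, 3, 1), cbind(1:3, 0))
  expect_equal(nrow(dispersion_clusters(zero, "g1", eps_um = 5)), 0)
  # two well-separated groups form two clusters; noise point discarded
  pts <- rbind(c(0, 0), c(3, 0), c(0, 3), c(100, 100), c(103, 100),
               c(100, 103), c(500, 500))
  two <- toy_counts(matrix(1, 7, 1), pts)
  res2 <- dispersion_clusters(two, "g1", eps_um = 5, min_pts = 3)
  expect_equal(sort(res2$n_spots), c(3, 3))
  # pairwise variant returns the variance of pairwise distances
  resp <- dispersion_clusters(col3, "g1", eps_um = 10, min_pts = 2,
                              variance = "pairwise")
  expect_equal(resp$distance_variance, var(c(1, 5, 4)))
})
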