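test_that("CF normalization maps the 1-63 kHz log range onto [0, 1]", {
  expect_equal(normalize_cf(1000), 0)
  expect_equal(normalize_cf(63000), 1)
  expect_equal(normalize_cf(8000), 3 / log2(63))
  expect_equal(normalize_cf(70000), 1)  # clipped, not discarded
  expect_error(normalize_cf(-5), "positive")
})

test_that("tonotopic index is the mean distance to the identity diagonal", {
  expect_equal(tonotopic_index(c(0, 0.5, 1), c(0, 0.5, 1)), 0)
  expect_equal(tonotopic_index(0, 1), 1 / sqrt(2))
  expect_equal(tonotopic_index(c(0, 0.5, 1), c(0.1, 0.6, 0.9)),
               0.1 / sqrt(2))
  expect_true(is.na(tonotopic_index(numeric(0), numeric(0))))
})

test_that("normalized axis handles rotation, reflection and degeneracy", {
  x <- c(0, 500, 1000); y <- c(200, 200, 200)
  expect_equal(normalized_axis(x, y), c(0, 0.5, 1))
  # same sites rigidly rotated by 30 degrees
  th <- pi / 6
  xr <- x * cos(th) - y * sin(th)
  yr <- x * sin(th) + y * cos(th)
  expect_equal(normalized_axis(xr, yr), c(0, 0.5, 1))
  # vertical flip with the CF-orientation rule applied
  cfn <- c(0.1, 0.5, 0.9)
  expect_equal(normalized_axis(x, -y, cfn), normalized_axis(x, y, cfn))
  # descending CFs flip the axis
  expect_equal(normalized_axis(x, y, rev(cfn)), c(1, 0.5, 0))
  # near-vertical maps are fit with swapped axes
  expect_equal(normalized_axis(y, x), c(0, 0.5, 1))
  expect_null(normalized_axis(c(0, 1), c(0, 1)))
  expect_null(normalized_axis(rep(1, 5), rep(2, 5)))
})

test_that("tonotopic index is rigid-motion invariant under the principal-axis fit", {
  opts <- analysis_options(axis_fit = "tls")
  set.seed(42)
  g <- map_geometry()
  cfn <- normalize_cf(pmin(pmax(1000 * 2^(g$x_um / 1000 +
                                            rnorm(128, 0, 0.5)), 1000), 63000))
  ti0 <- tonotopic_index(normalized_axis(g$x_um, g$y_um, cfn, opts), cfn)
  for (th in c(0.4, 1.2, 2.5)) {
    xr <- g$x_um * cos(th) - g$y_um * sin(th) + 300
    yr <- g$x_um * sin(th) + g$y_um * cos(th) - 150
    tir <- tonotopic_index(normalized_axis(xr, yr, cfn, opts), cfn)
    expect_equal(tir, ti0, tolerance = 1e-9)
  }
})

test_that("AI delineation applies the threshold, neighbor and VAF rules", {
  base <- tibble::tibble(
    penetration_id = 1L,
    grid_row = c(1L, 1L, 1L, 2L, 2L, 2L),
    grid_col = c(1L, 2L, 3L, 1L, 2L, 3L),
    x_um = (grid_col - 1) * 375, y_um = (grid_row - 1) * 500,
    responsive = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    cf_hz = c(4000, 8000, NA, 16000, 12000, 9000),
    threshold_db = c(30, 40, NA, 60, 20, 20),
    resp_above_30db = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE))
  ai <- delineate_ai(base)
  expect_false(ai[3])            # unresponsive
  expect_false(ai[6])            # VAF-like: nothing at or above 30 dB
  expect_true(all(ai[c(1, 2, 5)]))  # low-threshold AI core
  # high-threshold site 4 touches qualifying neighbors 1 (above) and 5 (right)
  expect_true(ai[4])
  # removing one neighbor breaks the rescue
  base2 <- base; base2$threshold_db[5] <- 60
  expect_false(delineate_ai(base2)[4])
})

test_that("AI delineation agrees with generator truth on a control cohort", {
  ds <- generate_cohort(n_control = 2, n_vpa = 0, seed = 21)
  an <- analyze_dataset(ds)
  tm <- dplyr::left_join(an$site_metrics, ds$truth, by = "site_id")
  expect_gte(mean(tm$in_ai == tm$is_ai), 0.85)
})

test_that("map tonotopy recovers an ordered gradient and flags jitter", {
  p <- make_protocol()
  smooth <- condition_preset("control", cf_jitter_oct_sd = 0,
                             hi_freq_bias = 0, p_non_ai = 0)
  tr <- sample_map(p, smooth, seed = 9)
  cfn <- normalize_cf(tr$true_cf_hz)
  pos <- normalized_axis(tr$x_um, tr$y_um, cfn)
  expect_lte(tonotopic_index(pos, cfn), 0.02)  # grid-quantization floor
})

test_that("Voronoi cells partition the hull and contain their sites", {
  # four corner sites with the unit square as hull: four quarter cells
  v <- voronoi_map(c(0, 0, 1, 1), c(0, 1, 0, 1),
                   hull = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(sort(v$sites$area_um2), rep(0.25, 4))
  expect_equal(sum(v$sites$area_um2), v$hull_area_um2, tolerance = 1e-9)
  # random map: cells tile the buffered hull; each cell's centroid is
  # nearest to its own site
  set.seed(3)
  x <- runif(30, 0, 3000); y <- runif(30, 0, 2000)
  v <- voronoi_map(x, y)
  expect_equal(sum(v$sites$area_um2), v$hull_area_um2,
               tolerance = 1e-6)
  cent <- t(vapply(v$cells, colMeans, numeric(2)))
  d2 <- as.matrix(stats::dist(rbind(cent, cbind(x, y))))[1:30, 31:60]
  expect_equal(unname(apply(d2, 1, which.min)), 1:30)
  expect_error(voronoi_map(1:5, 2 * (1:5)), "collinear")
  expect_error(voronoi_map(1, 1), "at least 3")
})

test_that("map figures render with CF fills and X/O marks", {
  g <- map_geometry(n_rows = 3, n_cols = 3, n_penetrations = 1)
  v <- voronoi_map(g$x_um, g$y_um, site_id = g$site_id)
  metrics <- tibble::tibble(
    responsive = c(rep(TRUE, 8), FALSE),
    in_ai = c(rep(TRUE, 7), FALSE, FALSE),
    cf_hz = c(2^seq(10, 16, length.out = 8) , NA))
  fig <- map_figure(v, metrics)
  expect_s3_class(fig, "ggplot")
})
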