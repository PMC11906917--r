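.rand_layout <- function(n = 30, seed = 7) {
  set.seed(seed)
  xy <- cbind(runif(n, -1, 1), runif(n, -1, 1))
  rows <- lapply(seq_len(n), function(i)
    data.frame(label = sprintf("c%02d", i),
               eccentricity = sqrt(sum(xy[i, ]^2)),
               angle = (atan2(xy[i, 2], xy[i, 1]) * 180 / pi) %% 360,
               x = xy[i, 1], y = xy[i, 2], stringsAsFactors = FALSE))
  scalplayout:::.layout_from_rows(rows, "test")
}

test_that("interpolation reproduces constants and affine fields", {
  lay <- .rand_layout(30)
  const <- interpolate_topo(lay, rep(3.5, 30))
  expect_true(all(abs(const$values[const$mask] - 3.5) < 1e-12))
  vals <- 2 * lay$x + 3 * lay$y
  img <- interpolate_topo(lay, setNames(vals, lay$label))
  truth <- outer(img$xgrid, img$ygrid, function(x, y) 2 * x + 3 * y)
  expect_lt(max(abs(img$values - truth), na.rm = TRUE), 1e-9)
  # masked pixels carry NA, never 0
  expect_true(anyNA(img$values))
  expect_false(any(img$values[!img$mask] == 0, na.rm = TRUE))
})

test_that("three channels interpolate their centroid to the mean", {
  xy <- rbind(c(-0.5, -0.4), c(0.6, -0.3), c(0, 0.7))
  rows <- lapply(1:3, function(i)
    data.frame(label = letters[i], eccentricity = 0, angle = 0,
               x = xy[i, 1], y = xy[i, 2], stringsAsFactors = FALSE))
  lay <- scalplayout:::.layout_from_rows(rows, "test")
  vals <- c(1, 2, 6)
  # use a raster having a pixel exactly at the centroid
  ctr <- colMeans(xy)
  img <- interpolate_topo(lay, vals, resolution = 241)
  i <- which.min(abs(img$xgrid - ctr[1]))
  j <- which.min(abs(img$ygrid - ctr[2]))
  expect_equal(img$values[i, j], mean(vals), tolerance = 0.05)
})

test_that("collinear channels cannot be interpolated", {
  rows <- lapply(1:4, function(i)
    data.frame(label = letters[i], eccentricity = 0, angle = 0,
               x = i / 10, y = i / 10, stringsAsFactors = FALSE))
  lay <- scalplayout:::.layout_from_rows(rows, "test")
  expect_error(interpolate_topo(lay, 1:4), class = "scalplayout_geometry_error")
})

test_that("perimeter extrapolation covers the full disc", {
  lay <- .rand_layout(20, seed = 3)
  img <- interpolate_topo(lay, rep(1, 20) + lay$x, extrapolate = "perimeter")
  g <- img$xgrid
  inside <- outer(g^2, g^2, `+`) <= 1.2^2
  expect_true(all(img$mask[inside]))
})

test_that("z-scoring standardises and is affine-invariant", {
  lay <- .rand_layout(25, seed = 9)
  img <- interpolate_topo(lay, rnorm(25))
  z <- zscore_image(img)
  v <- z$values[z$mask]
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-12)
  expect_identical(z$mask, img$mask)
  img2 <- img
  img2$values <- 4.2 * img2$values - 17
  expect_equal(zscore_image(img2)$values, z$values, tolerance = 1e-9)
  flat <- img
  flat$values[flat$mask] <- 5
  expect_error(zscore_image(flat), class = "scalplayout_geometry_error")
})

test_that("two-valued image z-scores to plus/minus one", {
  img <- structure(list(values = matrix(c(1, 3), 1), mask = c(TRUE, TRUE),
                        xgrid = 1:2, ygrid = 1, resolution = NA),
                   class = "topo_image")
  img$mask <- matrix(c(TRUE, TRUE), 1)
  z <- zscore_image(img)
  expect_equal(as.vector(z$values), c(-1, 1))
})

test_that("group t-map matches the hand-computed oracle", {
  lay <- .rand_layout(15, seed = 2)
  base <- interpolate_topo(lay, rnorm(15))
  mk <- function(k) { b <- base; b$values[b$mask] <- k; b }
  tm <- group_t_map(list(mk(1), mk(2), mk(3)))
  expect_equal(unique(round(tm$t[tm$mask], 9)), round(2 / (1 / sqrt(3)), 9))
  expect_true(all(tm$n_effective[tm$mask] == 3))
})

test_that("identical images yield flagged degenerate pixels, not infinities", {
  lay <- .rand_layout(15, seed = 4)
  img <- interpolate_topo(lay, rnorm(15))
  expect_error(group_t_map(list(img, img, img)), class = "scalplayout_input_error")
  # mixed case: some identical pixels within otherwise varying images
  i2 <- img
  i2$values <- img$values + 1
  mid <- ceiling(img$resolution / 2)
  i2$values[mid, ] <- img$values[mid, ]
  tm <- group_t_map(list(img, i2))
  expect_false(any(is.infinite(tm$t), na.rm = TRUE))
  expect_true(any(tm$degenerate, na.rm = TRUE))
})

test_that("sign flip of all inputs flips t", {
  lay <- .rand_layout(15, seed = 5)
  imgs <- lapply(1:4, function(k) interpolate_topo(lay, rnorm(15, mean = 1)))
  tm <- group_t_map(imgs)
  neg <- lapply(imgs, function(im) { im$values <- -im$values; im })
  tmn <- group_t_map(neg)
  expect_equal(tmn$t, -tm$t, tolerance = 1e-9)
})

test_that("channel subselection behaves per contract", {
  set.seed(1)
  X <- matrix(rnorm(60), ncol = 3) * 20
  rownames(X) <- sprintf("S%02d", 1:20)
  sens <- scalplayout:::.sensor_table(X)
  expect_setequal(subselect_channels(sens, 20, "sparse", seed = 3), sens$label)
  vals <- setNames(rnorm(20), sens$label)
  expect_setequal(subselect_channels(sens, 20, "focal", values = vals), sens$label)
  # focal always contains the peak and respects 3D proximity
  k <- names(which.max(vals))
  for (n in c(3, 8, 15))
    expect_true(k %in% subselect_channels(sens, n, "focal", values = vals))
  # sparse subsets are nested and reproducible under one seed
  s10 <- subselect_channels(sens, 10, "sparse", seed = 42)
  s6 <- subselect_channels(sens, 6, "sparse", seed = 42)
  expect_true(all(s6 %in% s10))
  expect_identical(s10, subselect_channels(sens, 10, "sparse", seed = 42))
  expect_error(subselect_channels(sens, 0, "sparse"),
               class = "scalplayout_input_error")
  expect_error(subselect_channels(sens, 21, "sparse"),
               class = "scalplayout_input_error")
})

test_that("run_comparison bookkeeping: one row per cell", {
  cohort <- fixture("mini_cohort", function()
    make_cohort(synthetic_head_spec(n_surface_points = 600), 3,
                n_sensors = 24, seed = 8))
  res <- run_comparison(cohort, 18, modes = "sparse", n_targets = 2, seed = 8)
  expect_equal(nrow(res), 2 * 1 * 2)   # methods x n_keep x targets
  expect_setequal(unique(res$method), c("anatomical", "polar"))
  expect_true(all(is.finite(res$mean_t)))
  # determinism under one seed
  res2 <- run_comparison(cohort, 18, modes = "sparse", n_targets = 2, seed = 8)
  expect_identical(res, res2)
})

test_that("anatomical mean_t is invariant to per-subject rigid motion", {
  cohort <- fixture("mini_cohort", function()
    make_cohort(synthetic_head_spec(n_surface_points = 600), 3,
                n_sensors = 24, seed = 8))
  moved <- lapply(seq_along(cohort), function(i) {
    R <- rotation_about(c(i, 1, 2), 20 + 5 * i)
    shift <- c(5 * i, -10, 3 * i)
    list(scan = transform_scan(cohort[[i]]$scan, R, shift),
         sensors = transform_sensors(cohort[[i]]$sensors, R, shift))
  })
  a0 <- run_comparison(cohort, 18, modes = "sparse", methods = "anatomical",
                       n_targets = 2, seed = 8)
  a1 <- run_comparison(moved, 18, modes = "sparse", methods = "anatomical",
                       n_targets = 2, seed = 8)
  expect_equal(a1$mean_t, a0$mean_t, tolerance = 1e-3)
  p0 <- run_comparison(cohort, 18, modes = "sparse", methods = "polar",
                       n_targets = 2, seed = 8)
  p1 <- run_comparison(moved, 18, modes = "sparse", methods = "polar",
                       n_targets = 2, seed = 8)
  expect_gt(max(abs(p1$mean_t - p0$mean_t)), 0.05)
})
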