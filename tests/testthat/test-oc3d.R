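test_that("thresholding separates a two-valued stack and rejects constants", {
  vox <- array(10, c(4, 8, 8)); vox[2, 3:5, 3:5] <- 200
  s <- calibrated_stack(vox, dx = 1, dz = 1)
  for (t in c(11, 100, 200)) {
    th <- global_threshold(s, "manual", value = t)
    expect_identical(th$mask, vox == 200)
  }
  const <- calibrated_stack(array(5, c(2, 4, 4)), dx = 1, dz = 1)
  expect_error(global_threshold(const, "otsu"), "manual")
})

test_that("half-max threshold covers >= 90% of each phantom nucleus", {
  ph <- clean_phantom(n_plant = 6, seed = 23)
  th <- global_threshold(ph$stack, "manual",
                         value = ph$truth$peak[1] / 2)
  for (o in seq_len(nrow(ph$truth))) {
    tr <- ph$truth[o, ]
    support <- raster_ellipsoid(dim(ph$stack$voxels),
                                c(ph$stack$dz, ph$stack$dy, ph$stack$dx),
                                c(tr$center_z_um, tr$center_y_um,
                                  tr$center_x_um),
                                c(tr$r_z_um, tr$r_y_um, tr$r_x_um))
    expect_gte(sum(th$mask & support) / sum(support), 0.9)
  }
})

test_that("depth attenuation erodes mask coverage monotonically", {
  ph <- generate_phantom(phantom_config(
    n_plant = 12, n_fungal = 0, n_wall = 0, poisson_noise = FALSE,
    read_noise_sd = 0, attenuation_um = 15, seed = 29))
  th <- global_threshold(ph$stack, "manual", value = ph$truth$peak[1] / 2)
  cov <- vapply(seq_len(nrow(ph$truth)), function(o) {
    tr <- ph$truth[o, ]
    support <- raster_ellipsoid(dim(ph$stack$voxels),
                                c(ph$stack$dz, ph$stack$dy, ph$stack$dx),
                                c(tr$center_z_um, tr$center_y_um,
                                  tr$center_x_um),
                                c(tr$r_z_um, tr$r_y_um, tr$r_x_um))
    sum(th$mask & support) / sum(support)
  }, 0)
  expect_lt(cor(ph$truth$center_z_um, cov, method = "spearman"), -0.7)
})

test_that("3D labeling matches a flood-fill oracle on small random stacks", {
  set.seed(31)
  s <- calibrated_stack(array(1, c(12, 12, 12)), dx = 1, dz = 1)
  for (conn in c(6L, 26L)) for (rep in 1:3) {
    mask <- array(runif(12^3) < 0.2, c(12, 12, 12))
    got <- label_components_3d(mask, s, connectivity = conn)$labels
    want <- flood_fill_oracle(mask, connectivity = conn)
    expect_true(same_partition(got, want))
    expect_equal(max(got), max(want))
  }
})

test_that("disjoint rasterized spheres are measured within 5% of analytic", {
  cal <- c(0.5, 0.3, 0.3)
  dims <- c(40L, 80L, 80L)
  m <- raster_ellipsoid(dims, cal, c(8, 8, 8), c(3, 3, 3)) |
    raster_ellipsoid(dims, cal, c(12, 16, 16), c(3, 3, 3))
  s <- calibrated_stack(array(1, dims), dx = 0.3, dy = 0.3, dz = 0.5)
  res <- label_components_3d(m, s)
  expect_equal(nrow(res$objects), 2L)
  analytic <- 4 / 3 * pi * 27
  expect_true(all(abs(res$objects$volume_um3 - analytic) / analytic < 0.05))
  expect_true(all(res$objects$lobedness < 0.05))
  # volume conservation: component volumes sum to mask voxels * voxel volume
  expect_equal(sum(res$objects$volume_um3), sum(m) * voxel_volume(s))
})

test_that("rasterization error shrinks with resolution", {
  errs <- vapply(c(0.6, 0.3), function(h) {
    dims <- c(ceiling(16 / h), ceiling(16 / h), ceiling(16 / h))
    m <- raster_ellipsoid(dims, rep(h, 3), c(8, 8, 8), c(4, 3.2, 3.6))
    vol <- sum(m) * h^3
    abs(vol - 4 / 3 * pi * 4 * 3.2 * 3.6) / (4 / 3 * pi * 4 * 3.2 * 3.6)
  }, 0)
  expect_lt(errs[1], 0.05)   # min radius > 5 voxels at h = 0.6
  expect_lt(errs[2], errs[1])
})

test_that("touching spheres merge into one lobed-flagged object", {
  cal <- c(0.5, 0.3, 0.3)
  dims <- c(40L, 80L, 80L)
  m <- raster_ellipsoid(dims, cal, c(10, 12, 9), c(3, 3, 3)) |
    raster_ellipsoid(dims, cal, c(10, 12, 9 + 5.95), c(3, 3, 3))
  s <- calibrated_stack(array(1, dims), dx = 0.3, dy = 0.3, dz = 0.5)
  res <- label_components_3d(m, s, connectivity = 26L)
  expect_equal(nrow(res$objects), 1L)
  expect_gt(res$objects$lobedness, 0.08)
  flagged <- filter_objects(res$objects, min_volume = 15, max_volume = 500,
                            drop_lobed = TRUE)
  expect_true(flagged$excluded)
  expect_equal(flagged$exclude_reason, "lobed")
})

test_that("raising the threshold never grows the mask", {
  ph <- generate_phantom(phantom_config(n_plant = 5, seed = 37))
  m1 <- global_threshold(ph$stack, "manual", value = 1000)$mask
  m2 <- global_threshold(ph$stack, "manual", value = 1600)$mask
  expect_true(all(m1[m2]))   # higher-threshold mask is a subset
})

test_that("exclusion flags are set without deleting objects", {
  obj <- data.frame(object_id = 1:3, voxel_count = c(10, 100, 100),
                    volume_um3 = c(5, 100, 100),
                    centroid_z_um = 0, centroid_y_um = 0, centroid_x_um = 0,
                    z0 = 0L, z1 = 1L, y0 = 0L, y1 = 1L, x0 = 0L, x1 = 1L,
                    touches_border = c(FALSE, TRUE, FALSE),
                    lobedness = c(0, 0, 0.3),
                    excluded = FALSE, exclude_reason = "")
  allpass <- filter_objects(obj, min_volume = 1, max_volume = 1000,
                            drop_border = FALSE, drop_lobed = FALSE)
  expect_false(any(allpass$excluded))
  strict <- filter_objects(obj, min_volume = 15, max_volume = 250,
                           drop_border = TRUE, drop_lobed = TRUE)
  expect_equal(nrow(strict), 3L)
  expect_equal(strict$exclude_reason, c("size", "border", "lobed"))
})

test_that("overlay preserves both channels and validates shapes", {
  ph <- clean_phantom(n_plant = 2, seed = 4, shape = c(8L, 64L, 64L))
  oc <- run_object_counter(ph$stack, threshold = "manual",
                           threshold_value = 1500)
  ov <- overlay_map(ph$stack, oc$labels)
  expect_identical(ov$intensity, ph$stack$voxels)
  expect_identical(ov$labels, oc$labels)
  expect_error(overlay_map(ph$stack, array(0L, c(2, 2, 2))), "shape")
  empty <- overlay_map(ph$stack, array(0L, dim(ph$stack$voxels)))
  expect_identical(empty$intensity, ph$stack$voxels)
  path <- tempfile(fileext = ".tif")
  write_overlay(ov, path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  expect_length(pages, 2L * dim(ph$stack$voxels)[1])
  label_pages <- pages[seq(2, length(pages), by = 2)]
  expect_equal(max(unlist(label_pages)), max(oc$labels))  # ids preserved
})

test_that("the volumetric pipeline recovers phantom volumes within 10%", {
  ph <- clean_phantom(n_plant = 10, seed = 42)
  oc <- run_object_counter(ph$stack, threshold = "manual",
                           threshold_value = 1500)
  expect_equal(nrow(oc$table), 10L)
  bm <- benchmark_methods(ph$truth, oc$table)
  expect_equal(bm$recall, 1)
  expect_true(all(abs(bm$errors$volume_rel_error) < 0.10))
  # determinism: identical reruns give identical tables
  oc2 <- run_object_counter(ph$stack, threshold = "manual",
                            threshold_value = 1500)
  expect_identical(oc$table, oc2$table)
})

test_that("fungal-sized components are excluded by the volume gate", {
  ph <- generate_phantom(phantom_config(
    n_plant = 6, n_fungal = 5, n_wall = 0, poisson_noise = FALSE,
    read_noise_sd = 0, attenuation_um = Inf, seed = 11))
  oc <- run_object_counter(ph$stack, threshold = "manual",
                           threshold_value = ph$truth$peak[
                             ph$truth$kind == "fungal_nucleus"][1] / 2,
                           min_volume = 15)
  fungal <- ph$truth[ph$truth$kind == "fungal_nucleus", ]
  for (r in seq_len(nrow(fungal))) {
    d <- sqrt((oc$table$centroid_z_um - fungal$center_z_um[r])^2 +
                (oc$table$centroid_y_um - fungal$center_y_um[r])^2 +
                (oc$table$centroid_x_um - fungal$center_x_um[r])^2)
    expect_true(all(d > 3))
  }
  expect_gte(oc$excluded_counts[["size"]], nrow(fungal))
})
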