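test_that("generation is a pure function of config and seed", {
  cfg <- tiny_phantom(seed = 7)
  b1 <- generate_normal_bscan(cfg, 2)
  b2 <- generate_normal_bscan(cfg, 2)
  expect_identical(b1, b2)
  v1 <- generate_volume(cfg)
  v2 <- generate_volume(cfg)
  expect_identical(v1$images, v2$images)
  ## different seeds give different images
  b3 <- generate_normal_bscan(tiny_phantom(seed = 8), 2)
  expect_false(identical(b1$image, b3$image))
})

test_that("noiseless limit yields piecewise-constant bands at the configured reflectivities", {
  cfg <- tiny_phantom(seed = 3, speckle_shape = Inf)
  b <- generate_normal_bscan(cfg, 1)
  vals <- sort(unique(as.vector(b$image)))
  expected <- sort(unique(c(cfg$background_intensity, cfg$layer_reflectivities)))
  expect_equal(vals, expected)
  ## every band contains its reflectivity
  for (r in cfg$layer_reflectivities) expect_true(any(b$image == r))
})

test_that("boundaries are strictly increasing per column across many seeds", {
  for (seed in 1:100) {
    cfg <- phantom_config(height = 24L, width = 16L, n_layers = 4L,
                          n_bscans = 1L, seed = seed)
    b <- generate_normal_bscan(cfg, 1)
    expect_true(all(apply(b$boundaries, 2, function(x) all(diff(x) > 0))),
                info = paste("seed", seed))
  }
})

test_that("lesion specs are validated", {
  expect_error(lesion_spec("bump", c(10, 10), 0), "target_area")
  expect_error(lesion_spec("bump", c(0, 10), 50), "center")
  expect_error(lesion_spec("wobble", c(10, 10), 50))
  cfg <- tiny_phantom(seed = 1)
  b <- generate_normal_bscan(cfg, 1)
  expect_error(
    inject_lesion(b$image, b$boundaries, lesion_spec("bump", c(100, 100), 50), 1),
    "outside"
  )
  ## minimal valid lesion still modifies at least one pixel
  r <- inject_lesion(b$image, b$boundaries, lesion_spec("bump", c(16, 16), 4), 1)
  expect_gte(sum(r$mask), 1)
})

test_that("fluid pockets darken the masked pixels", {
  cfg <- phantom_config(seed = 5)
  b <- generate_normal_bscan(cfg, 1)
  spec <- lesion_spec("fluid_pocket", c(32, 32), 200, intensity_shift = -0.5)
  r <- inject_lesion(b$image, b$boundaries, spec, seed = 2)
  idx <- r$mask == 1
  expect_lt(mean(r$image[idx]), mean(b$image[idx]))
})

test_that("realized mask areas stay within 20% of the target", {
  cfg <- phantom_config(seed = 9)
  b <- generate_normal_bscan(cfg, 1)
  for (kind in c("bump", "fluid_pocket", "deformation")) {
    spec <- lesion_spec(kind, c(32, 32), 400,
                        intensity_shift = if (kind == "fluid_pocket") -0.5 else 0.3)
    r <- inject_lesion(b$image, b$boundaries, spec, seed = 4, config = cfg)
    area <- sum(r$mask)
    expect_gte(area, 320)
    expect_lte(area, 480)
    ## and the mask marks genuinely modified pixels
    expect_gt(mean(abs(r$image - b$image)[r$mask == 1]), 0)
  }
})

test_that("volume labels and lesion areas are derived from the masks", {
  cfg <- tiny_phantom(seed = 11)
  v0 <- generate_volume(cfg)
  expect_equal(v0$label, "normal")
  expect_true(all(v0$lesion_areas$lesion_area_px == 0))
  specs <- rep(list(list()), cfg$n_bscans)
  specs[[2]] <- list(lesion_spec("fluid_pocket", c(16, 16), 60, -0.5))
  v1 <- generate_volume(cfg, specs)
  expect_equal(v1$label, "anomalous")
  ## recount positive pixels independently
  recount <- vapply(v1$masks, function(m) sum(m > 0), numeric(1))
  expect_identical(as.numeric(v1$lesion_areas$lesion_area_px), recount)
  expect_equal(v1$lesion_areas$relative_lesion_area,
               recount / (cfg$height * cfg$width))
  expect_error(generate_volume(cfg, specs[1:2]), "per B-scan")
})

test_that("datasets round-trip through disk", {
  cfg <- tiny_phantom(seed = 13)
  specs <- rep(list(list()), cfg$n_bscans)
  specs[[1]] <- list(lesion_spec("bump", c(16, 16), 60, 0.3))
  vols <- list(generate_volume(cfg, NULL, volume_id = "v1"),
               generate_volume(cfg, specs, volume_id = "v2"))
  d8 <- withr::local_tempdir()
  man <- write_dataset(vols, d8, depth = "8")
  expect_equal(nrow(man), 2L * cfg$n_bscans)
  back <- read_dataset(d8)
  expect_identical(back$volumes[["v2"]]$masks, vols[[2]]$masks)
  expect_lt(max(abs(back$volumes[["v1"]]$images[[1]] - vols[[1]]$images[[1]])),
            1 / 255 + 1e-9)
  ## 16-bit mode: quantization error bounded by one 16-bit step
  d16 <- withr::local_tempdir()
  write_dataset(vols, d16, depth = "16")
  back16 <- read_dataset(d16)
  expect_lte(max(abs(back16$volumes[["v1"]]$images[[1]] - vols[[1]]$images[[1]])),
             1 / 65535)
  ## labels in the manifest match the masks
  expect_identical(man$label,
                   ifelse(man$lesion_area_px > 0, "anomalous", "normal"))
})

test_that("study sets are labelled, reproducible, and span the lesion-size range", {
  cfg <- tiny_phantom(seed = 1)
  vols <- simulate_study_set(3, 4, cfg, seed = 5, lesion_areas = c(30, 120))
  expect_length(vols, 7L)
  labs <- vapply(vols, `[[`, character(1), "label")
  expect_identical(unname(labs), c(rep("normal", 3), rep("anomalous", 4)))
  vols2 <- simulate_study_set(3, 4, cfg, seed = 5, lesion_areas = c(30, 120))
  expect_identical(vols[[5]]$images, vols2[[5]]$images)
})
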