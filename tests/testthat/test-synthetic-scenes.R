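clean_cfg <- function(...) {
  scene_config(psf_sigma_nm = 0, background_level = 0, poisson_scale = 0,
               gaussian_sd = 0, ...)
}

test_that("an empty scene is pure background and truth has zero objects", {
  scn <- generate_scene(scene_config(n_green = 0, n_red = 0, n_hybrid = 0,
                                     psf_sigma_nm = 0, poisson_scale = 0,
                                     gaussian_sd = 0, background_level = 5,
                                     seed = 1))
  expect_true(all(scn$stack$pixels == 5))
  expect_equal(nrow(scn$truth$objects), 0)
  expect_equal(unname(scn$truth$true_counts), c(0L, 0L))
})

test_that("identical config and seed reproduce a bit-identical scene", {
  cfg <- scene_config(n_green = 20, n_red = 5, n_hybrid = 3, seed = 99)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$stack$pixels, b$stack$pixels)
  expect_identical(a$truth$objects, b$truth$objects)
})

test_that("noiseless render has exactly the true number of disjoint components", {
  scn <- generate_scene(clean_cfg(n_green = 150, placement = "scattered",
                                  seed = 21))
  expect_equal(unname(scn$truth$true_counts["green"]), 150L)
  proj <- max_projection(scn$stack, "green")
  lab <- flood_fill_labels(proj$pixels > 0)
  expect_equal(max(lab), 150L)
})

test_that("geometric overlap truth matches a fine-grid rasterization audit", {
  scn <- generate_scene(clean_cfg(n_green = 12, n_red = 8, n_hybrid = 6,
                                  placement = "scattered", seed = 5))
  obj <- scn$truth$objects
  expect_equal(scn$truth$true_overlap$red_to_green,
               raster_overlap_frac(obj, "red", "green"))
  expect_equal(scn$truth$true_overlap$green_to_red,
               raster_overlap_frac(obj, "green", "red"))
  # construction: exactly the hybrid-attached red domains touch green
  expect_equal(scn$truth$true_overlap$red_to_green, 6 / (8 + 6))
})

test_that("hybrid domains always partially overlap after blur and binarization", {
  scn <- generate_scene(scene_config(n_green = 0, n_red = 0, n_hybrid = 8,
                                     placement = "scattered",
                                     poisson_scale = 0, gaussian_sd = 0,
                                     background_level = 0, seed = 13))
  z <- base_plane_slice(scn$stack)
  g <- single_slice(scn$stack, "green", z)$pixels > 1
  r <- single_slice(scn$stack, "red", z)$pixels > 1
  expect_true(sum(g & r) >= 8)     # each pair shares pixels
  expect_true(any(g & !r) && any(r & !g))  # domains stay distinct
})

test_that("scene background and amplitude statistics are recoverable", {
  cfg <- scene_config(n_green = 10, placement = "scattered",
                      background_level = 20, amplitude_range = c(150, 150),
                      psf_sigma_nm = 0, seed = 31)
  scn <- generate_scene(cfg)
  px <- scn$stack$pixels[1, 3, , ]          # base plane, green
  bg <- px[px < 75]
  expect_lt(abs(mean(bg) - 20), 3 * sd(bg) / sqrt(length(bg)) + 0.5)
  fg <- px[px >= 75]
  expect_lt(abs(mean(fg) - 170), 5)
})

test_that("timecourse targets are met by integer rounding of attached reds", {
  sc <- timecourse_scenario(c("a", "b"), c(0.6, 0), n_red_total = 10,
                            base_config = clean_cfg(n_green = 15,
                                                    placement = "scattered"),
                            seed = 2)
  scenes <- generate_timecourse(sc)
  # 60% of 10 -> exactly 6 attached
  expect_equal(scenes[[1]]$truth$true_overlap$red_to_green, 0.6)
  # target 0 -> all reds clear of green
  expect_equal(scenes[[2]]$truth$true_overlap$red_to_green, 0)
  expect_error(timecourse_scenario(c("a"), 1.2), "\\[0, 1\\]")
  expect_error(timecourse_scenario(c("a", "a"), c(0, 0)), "unique")
})

test_that("full-attachment target makes every red object a hybrid domain", {
  sc <- timecourse_scenario("t", 1.0, n_red_total = 10,
                            base_config = clean_cfg(n_green = 5,
                                                    placement = "scattered"),
                            seed = 3)
  scn <- generate_timecourse(sc)[[1]]
  expect_equal(scn$truth$true_overlap$red_to_green, 1.0)
  obj <- scn$truth$objects
  expect_true(all(obj$hybrid[obj$channel == "red"]))
})

test_that("densitometry generator honours effects and determinism", {
  tp <- c("0", "15", "30")
  noiseless <- generate_densitometry(tp, n_reps = 3, effect = c(1, 1, 1),
                                     noise_cv = 0, seed = 1)
  fc <- densitometry_foldchange(noiseless, "0")
  expect_true(all(fc$fold_change == 1))
  dbl <- generate_densitometry(tp, 3, effect = c(1, 2, 1), noise_cv = 0,
                               seed = 1)
  fc2 <- densitometry_foldchange(dbl, "0")
  expect_equal(unique(fc2$fold_change[fc2$timepoint == "15"]), 2)
  a <- generate_densitometry(tp, 3, noise_cv = 0.2, seed = 7)
  b <- generate_densitometry(tp, 3, noise_cv = 0.2, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$band_density > 0 & a$loading_density > 0))
})

test_that("scenes round-trip through TIFF plus truth sidecar", {
  scn <- generate_scene(scene_config(n_green = 6, n_hybrid = 2,
                                     placement = "scattered", seed = 17))
  dir <- withr::local_tempdir()
  paths <- write_scene(scn, dir, "cell01")
  expect_true(all(file.exists(paths)))
  truth <- read_scene_truth(paths[["truth"]])
  expect_equal(truth$true_counts, scn$truth$true_counts)
  expect_equal(truth$true_overlap, scn$truth$true_overlap)
  back <- read_stack(paths[["tiff"]], 100, channel_names = c("green", "red"))
  expect_equal(dim(back$pixels), dim(scn$stack$pixels))
  # written stack is the 8-bit clipped render
  expect_equal(back$pixels[1, 3, , ],
               pmin(pmax(round(scn$stack$pixels[1, 3, , ]), 0), 255))
})

test_that("overcrowded configurations fail with a placement error", {
  cfg <- scene_config(image_shape = c(40L, 40L), n_green = 200,
                      placement = "scattered", seed = 1)
  expect_error(generate_scene(cfg), "placement failed")
})
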