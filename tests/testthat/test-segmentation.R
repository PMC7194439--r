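test_that("median subtraction of a constant image is zero everywhere", {
  out <- median_subtract(as_img(matrix(37, 20, 20)), 6)
  expect_true(all(out$pixels == 0))
})

test_that("an isolated bright pixel survives subtraction; neighbours stay 0", {
  # radius-1 disk = centre + 4-neighbourhood (5 px); the local median at the
  # bright pixel is 0, so it keeps its full value
  m <- matrix(0, 9, 9); m[5, 5] <- 80
  out <- median_subtract(as_img(m), 1)
  expect_equal(out$pixels[5, 5], 80)
  expect_true(all(out$pixels[-41] == 0))
})

test_that("pixels below their local median clamp to zero (and only on request)", {
  m <- matrix(50, 9, 9); m[5, 5] <- 10   # a dark pit
  out <- median_subtract(as_img(m), 1, clamp_negative = TRUE)
  expect_equal(out$pixels[5, 5], 0)
  out2 <- median_subtract(as_img(m), 1, clamp_negative = FALSE)
  expect_equal(out2$pixels[5, 5], -40)   # raw difference preserved
  expect_true(all(out2$pixels[-41] == 0))
})

test_that("median radius beyond the image half-extent is rejected", {
  expect_error(median_subtract(as_img(matrix(0, 10, 10)), 5), "half-extent")
  expect_error(median_subtract(as_img(matrix(0, 10, 10)), 0), ">= 1")
})

test_that("subtraction output is invariant to a constant intensity offset", {
  set.seed(8)
  m <- matrix(sample(0:100, 400, TRUE), 20, 20)
  a <- median_subtract(as_img(m), 3)$pixels
  b <- median_subtract(as_img(m + 55), 3)$pixels
  expect_equal(a, b)
})

test_that("disk median matches a brute-force neighbourhood median", {
  set.seed(12)
  m <- matrix(sample(0:255, 15 * 15, TRUE), 15, 15)
  r <- 2
  med <- m - median_subtract(as_img(m), r, clamp_negative = FALSE)$pixels
  # brute force at interior pixels (reflection irrelevant there)
  for (y in (r + 1):(15 - r)) for (x in (r + 1):(15 - r)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r)
      if (dy^2 + dx^2 <= r^2) vals <- c(vals, m[y + dy, x + dx])
    expect_equal(med[y, x], median(vals))
  }
})

test_that("fixed and correspondence threshold modes behave as declared", {
  expect_equal(select_threshold(as_img(matrix(1:4, 2, 2)),
                                as_img(matrix(1:4, 2, 2)),
                                "fixed", fixed_threshold = 50), 50)
  # separable case: two-valued enhanced image matching bright blobs
  enh <- matrix(0, 10, 10); enh[3:5, 3:5] <- 200
  orig <- matrix(10, 10, 10); orig[3:5, 3:5] <- 180
  thr <- select_threshold(as_img(enh), as_img(orig), "correspondence")
  expect_equal(as_img(enh)$pixels > thr, enh > 0)  # recovers exactly the blobs
  expect_error(select_threshold(as_img(matrix(5, 4, 4)), as_img(matrix(5, 4, 4)),
                                "correspondence"),
               class = "endoquant_degenerate_image")
})

test_that("correspondence threshold equals an exhaustive-scan oracle", {
  set.seed(41)
  scn <- generate_scene(scene_config(n_green = 12, placement = "scattered",
                                     seed = 41))
  img <- to_8bit(max_projection(scn$stack, "green"))
  enh <- median_subtract(img, 6)
  got <- select_threshold(enh, img, "correspondence")
  # oracle: literal scan of every integer threshold, cor() per candidate
  cand <- seq(floor(min(enh$pixels)), ceiling(max(enh$pixels)) - 1)
  cors <- vapply(cand, function(t) {
    m <- as.numeric(enh$pixels > t)
    if (sum(m) == 0 || sum(m) == length(m)) return(-Inf)
    cor(m, as.numeric(img$pixels))
  }, numeric(1))
  expect_equal(got, cand[which.max(cors)])
})

test_that("binarization is strictly greater-than", {
  img <- as_img(matrix(c(10, 20, 10, 20), 2, 2))
  bm <- binarize(img, 10)
  expect_equal(bm$mask, matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_equal(bm$threshold_used, 10)
  expect_true(all(!binarize(img, 20)$mask))   # threshold >= max -> empty
  expect_true(all(binarize(img, 9)$mask))     # threshold < min -> full
})

test_that("area filter is strict at the 20000 nm^2 boundary (100 nm px)", {
  m <- matrix(FALSE, 12, 12)
  m[2, 2:3] <- TRUE            # 2 px = 20000 nm^2: NOT larger -> dropped
  m[6, 2:4] <- TRUE            # 3 px = 30000 nm^2: kept
  bm <- binarize(as_img(m * 1), 0)
  lo <- extract_objects(bm, 20000)
  expect_equal(lo$n_objects, 1L)
  expect_equal(lo$pixel_counts, 3L)
})

test_that("labelling is 8-connected and matches a flood-fill oracle", {
  set.seed(77)
  m <- matrix(runif(900) < 0.3, 30, 30)
  lo <- extract_objects(binarize(as_img(m * 1), 0), min_area_nm2 = 0)
  oracle <- flood_fill_labels(m)
  expect_equal(lo$n_objects, max(oracle))
  # same partition: labels agree up to renaming
  expect_equal(length(unique(paste(lo$labels[m], oracle[m]))), max(oracle))
  # diagonal-only pair is one object
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(extract_objects(binarize(as_img(d * 1), 0), 0)$n_objects, 1L)
})

test_that("five disjoint blobs give five objects; empty mask gives none", {
  m <- matrix(FALSE, 20, 20)
  for (k in 0:4) m[k * 4 + 1, 1:5] <- TRUE
  lo <- extract_objects(binarize(as_img(m * 1), 0), 20000)
  expect_equal(lo$n_objects, 5L)
  expect_equal(lo$pixel_counts, rep(5L, 5))
  empty <- extract_objects(binarize(as_img(matrix(0, 5, 5)), 0), 20000)
  expect_equal(empty$n_objects, 0L)
})

test_that("raising the minimum area never increases the object count", {
  set.seed(9)
  m <- matrix(runif(400) < 0.35, 20, 20)
  bm <- binarize(as_img(m * 1), 0)
  counts <- vapply(seq(0, 2e5, by = 1e4),
                   function(a) extract_objects(bm, a)$n_objects, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("segment_channel recovers ground-truth counts on a clean scene", {
  scn <- generate_scene(scene_config(n_green = 25, placement = "scattered",
                                     psf_sigma_nm = 0, poisson_scale = 0,
                                     gaussian_sd = 0, seed = 3))
  img <- to_8bit(max_projection(scn$stack, "green"))
  seg <- segment_channel(img, seg_config(), "green")
  expect_equal(seg$n_objects, 25L)
  # determinism
  seg2 <- segment_channel(img, seg_config(), "green")
  expect_identical(seg$labels, seg2$labels)
  # all-background image yields zero objects, not an error
  flat <- segment_channel(as_img(matrix(3, 40, 40)), seg_config(), "green")
  expect_equal(flat$n_objects, 0L)
  expect_error(segment_channel(img, seg_config(), "magenta"), "no median radius")
})

test_that("median-subtraction resists blur-induced area inflation better than raw Otsu", {
  scn <- generate_scene(scene_config(n_green = 30, placement = "scattered",
                                     psf_sigma_nm = 300, seed = 55))
  img <- to_8bit(max_projection(scn$stack, "green"))
  true_area <- mean(pi * scn$truth$objects$radius_nm^2)
  med <- segment_channel(img, seg_config(), "green")
  a_med <- mean(measure_objects(med, img)$area_nm2)
  raw <- extract_objects(binarize(img, select_threshold(img, img, "otsu")),
                         20000, "green")
  a_raw <- mean(measure_objects(raw, img)$area_nm2)
  expect_lt(abs(a_med - true_area), abs(a_raw - true_area))
})
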