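test_that("classification applies the brightness-then-red-channel rule", {
  expect_equal(as.integer(classify_pixels(pixel_image(200, 120, 120), 0,
                                          red_threshold = 150,
                                          dark_threshold = 60)), 1L)  # live
  expect_equal(as.integer(classify_pixels(pixel_image(30, 30, 30), 0,
                                          red_threshold = 150,
                                          dark_threshold = 60)), 3L)  # interstice
  expect_equal(as.integer(classify_pixels(pixel_image(100, 120, 120), 0,
                                          red_threshold = 150,
                                          dark_threshold = 60)), 2L)  # dead
  # trace length must match image width
  expect_error(classify_pixels(pixel_image(1, 1, 1), c(0, 0)), "width")
})

test_that("noiseless synthetic images classify identically to scene truth", {
  sc <- small_scene(composition = c(0.45, 0.35, 0.2),
                    interface = interface_ramp(20, 120), seed = 21)
  mask <- classify_pixels(sc$image, sc$trace)
  expect_identical(as.integer(mask), as.integer(sc$truth$mask))
})

test_that("classification stays above 99% accuracy under channel noise", {
  cm <- color_model(channel_sd = 10)
  sc <- small_scene(color_model = cm, seed = 31, width = 200, height = 400)
  mask <- classify_pixels(sc$image, sc$trace, cm$red_threshold,
                          cm$dark_threshold)
  below <- unclass(sc$truth$mask) != 0L
  acc <- mean(unclass(mask)[below] == unclass(sc$truth$mask)[below])
  expect_gte(acc, 0.99)
})

test_that("rugosity matches its closed forms and is translation invariant", {
  expect_equal(interface_rugosity(rep(200, 120)), 0)
  W <- 100
  expect_equal(interface_rugosity(0:(W - 1)), (W - 1) / W)
  expect_equal(interface_rugosity(rep(c(100, 110), 50)), 9.9)
  tr <- c(5, 9, 3, 14, 8)
  expect_equal(interface_rugosity(tr + 7), interface_rugosity(tr))
})

test_that("penetration depth uses the mean interface position", {
  expect_equal(penetration_depth(rep(0, 10), 1090, 0.02), 21.8)
  expect_equal(penetration_depth(rep(545, 10), 1090, 0.02), 10.9)
  expect_equal(penetration_depth(c(100, 300), 1000, 0.02), 16.0)
})

test_that("live/dead ratio counts areas and flags the undefined case", {
  sc <- small_scene(composition = c(0.5, 0.3, 0.2))
  r <- live_dead_ratio(classify_pixels(sc$image, sc$trace))
  expect_equal(r$ratio, 0.5 / 0.3, tolerance = 1e-12)
  expect_true(r$defined)

  nodead <- small_scene(composition = c(0.7, 0, 0.3))
  r0 <- live_dead_ratio(classify_pixels(nodead$image, nodead$trace))
  expect_false(r0$defined)
  expect_true(is.na(r0$ratio))

  nolive <- small_scene(composition = c(0, 0.8, 0.2))
  expect_equal(live_dead_ratio(classify_pixels(nolive$image,
                                               nolive$trace))$ratio, 0)
})

test_that("vertical profiles close to 100% and recover banded truth exactly", {
  bands <- rbind(c(0.8, 0.1, 0.1), c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3))
  sc <- small_scene(composition = bands)
  mask <- classify_pixels(sc$image, sc$trace)
  pr <- vertical_profiles(mask, sc$trace, 0.02)
  sums <- pr$pct_live + pr$pct_dead + pr$pct_interstice
  expect_true(all(abs(sums[pr$n_px > 0] - 100) < 1e-9))
  tru <- sc$truth$profiles
  expect_equal(pr$pct_live, 100 * tru$frac_live)
  expect_equal(pr$pct_dead, 100 * tru$frac_dead)
  expect_equal(pr$pct_interstice, 100 * tru$frac_interstice)
  # first bands hold the prescribed fractions exactly (2500 px per bin)
  expect_equal(pr$pct_live[1:3], c(80, 50, 20))
})

test_that("bin occupancy matches brute-force pixel enumeration", {
  sc <- small_scene(interface = interface_flat(7), width = 30, height = 130)
  mask <- classify_pixels(sc$image, sc$trace)
  pr <- vertical_profiles(mask, sc$trace, 0.02)
  # brute force: count below-interface pixels per 25-row bin per column
  counts <- integer(nrow(pr))
  for (col in 1:30) for (row in 1:130) {
    d <- (row - 1) - sc$trace[col]
    if (d >= 0) {
      b <- floor(d * 0.02 / 0.5 + 1e-9) + 1
      counts[b] <- counts[b] + 1L
    }
  }
  expect_equal(pr$n_px, counts)
})

test_that("profiles are invariant to flattening the interface deeper", {
  sc <- small_scene(interface = interface_sine(60, 15, 0.3), seed = 13,
                    height = 400)
  mask <- classify_pixels(sc$image, sc$trace)
  pr1 <- vertical_profiles(mask, sc$trace, 0.02, max_depth_cm = 4)

  shift <- 50
  sc2 <- small_scene(interface = sc$trace + shift, seed = 13, height = 400)
  mask2 <- classify_pixels(sc2$image, sc2$trace)
  pr2 <- vertical_profiles(mask2, sc2$trace, 0.02, max_depth_cm = 4)
  expect_equal(pr2[, c("pct_live", "pct_dead", "pct_interstice")],
               pr1[, c("pct_live", "pct_dead", "pct_interstice")])
  expect_equal(penetration_depth(sc2$trace, 400, 0.02),
               penetration_depth(sc$trace, 400, 0.02) - shift * 0.02)
  expect_equal(interface_rugosity(sc2$trace), interface_rugosity(sc$trace))
})

test_that("every below-interface pixel receives exactly one class", {
  for (seed in 1:3) {
    sc <- small_scene(interface = interface_walk(80, 3, band = 30),
                      color_model = color_model(channel_sd = 12), seed = seed,
                      width = 60, height = 150)
    mask <- unclass(classify_pixels(sc$image, sc$trace))
    below <- outer(1:150, sc$trace, function(r, y) (r - 1) >= y)
    expect_true(all(mask[below] %in% 1:3))
    expect_true(all(mask[!below] == 0L))
  }
})

test_that("threshold calibration recovers a separable threshold", {
  set.seed(5)
  red <- c(rnorm(300, 220, 8), rnorm(300, 150, 8))
  is_live <- rep(c(TRUE, FALSE), each = 300)
  thr <- calibrate_red_threshold(red, is_live)
  expect_gt(thr, 160)
  expect_lt(thr, 210)
  # perfect separation at sd -> 0: any threshold in [150, 219] is error-free
  thr0 <- calibrate_red_threshold(c(220, 220, 150, 150),
                                  c(TRUE, TRUE, FALSE, FALSE))
  expect_gte(thr0, 150)
  expect_lt(thr0, 220)
})
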