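test_that("noiseless flat-interface all-live scene classifies entirely live", {
  sc <- small_scene(composition = c(1, 0, 0), interface = interface_flat(200),
                    height = 400)
  mask <- classify_pixels(sc$image, sc$trace)
  below <- mask[201:400, ]
  expect_true(all(below == 1L))
  expect_true(all(mask[1:200, ] == 0L))
})

test_that("constant banded composition yields exactly constant true profiles", {
  # width 100, flat interface, 25-row bins -> 2500 px per bin: 50/30/20 exact
  sc <- small_scene(composition = c(0.5, 0.3, 0.2))
  pr <- sc$truth$profiles
  expect_equal(pr$frac_live, rep(0.5, nrow(pr)))
  expect_equal(pr$frac_dead, rep(0.3, nrow(pr)))
  expect_equal(pr$frac_interstice, rep(0.2, nrow(pr)))
})

test_that("stored rugosity truth equals the closed formula on the trace", {
  sc <- small_scene(interface = interface_sine(150, c(20, 5), c(0.5, 0.13)),
                    seed = 11)
  S <- sum(abs(diff(sc$trace)))
  expect_identical(sc$truth$rugosity, S / length(sc$trace))
  expect_identical(sc$truth$penetration_cm,
                   (300 - mean(sc$trace)) * 0.02)
})

test_that("scene generation is deterministic and validates its inputs", {
  a <- small_scene(color_model = color_model(channel_sd = 10), seed = 3)
  b <- small_scene(color_model = color_model(channel_sd = 10), seed = 3)
  expect_identical(a, b)
  c <- small_scene(color_model = color_model(channel_sd = 10), seed = 4)
  expect_false(identical(a$image, c$image))
  expect_error(small_scene(interface = interface_flat(500)), "outside")
  expect_error(small_scene(composition = c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("thalli generator returns analytic truths for known polygons", {
  sq <- generate_thalli_image(list(poly_square(10, c(20, 20))), c(50, 50))
  expect_equal(sq$truth$perimeter, 40)
  expect_equal(sq$truth$solidity, 1)
  # plus of five unit squares at arm 30 px: area 5a^2, hull 7a^2
  pl <- generate_thalli_image(list(poly_plus(30, c(60, 60))), c(120, 120))
  expect_equal(pl$truth$area, 5 * 30^2)
  expect_equal(pl$truth$convex_area, 7 * 30^2)
  expect_equal(pl$truth$solidity, 5 / 7)
  # empty shape list
  em <- generate_thalli_image(list(), c(30, 30))
  expect_equal(nrow(em$truth), 0)
  expect_true(all(em$image <= 10))
  # overlap rejected
  expect_error(
    generate_thalli_image(list(poly_square(20, c(20, 20)),
                               poly_square(20, c(25, 25))), c(60, 60)),
    "overlap")
})

test_that("AIS generator truth follows the swept-area formula", {
  grid <- define_grid(c(0, 0), 50, 2, 2)
  tr <- generate_ais_tracks(make_pass(1, "V1", "s1", 3.5, c(0, 25), c(50, 25)),
                            grid)
  expect_equal(tr$truth$swept_m2, 75)
  expect_equal(tr$truth[, c("row", "col")], data.frame(row = 1L, col = 1L),
               ignore_attr = TRUE)
  # same pass outside the window sweeps nothing
  tr6 <- generate_ais_tracks(make_pass(1, "V1", "s1", 6, c(0, 25), c(50, 25)),
                             grid)
  expect_equal(nrow(tr6$truth), 0)
  expect_error(generate_ais_tracks(make_pass(1, "V1", "s1", 3.5, c(0, 0),
                                             c(10, 0)), grid,
                                   ping_interval_s = 0),
               "ping_interval_s")
})

test_that("swept-area truth is additive across seasons", {
  grid <- define_grid(c(0, 0), 50, 2, 3)
  whole <- generate_ais_tracks(
    make_pass(1, "V1", "s1", 3.5, c(10, 25), c(110, 25)), grid)
  split <- generate_ais_tracks(rbind(
    make_pass(1, "V1", "s1", 3.5, c(10, 25), c(60, 25)),
    make_pass(2, "V1", "s2", 3.5, c(60, 25), c(110, 25))), grid)
  per_cell_whole <- aggregate(swept_m2 ~ row + col, whole$truth, sum)
  per_cell_split <- aggregate(swept_m2 ~ row + col, split$truth, sum)
  expect_equal(per_cell_split, per_cell_whole)
})

test_that("campaign emits the prescribed design and grouping", {
  camp <- generate_campaign(gradient_spec(seed = 2), with_tracks = FALSE)
  expect_equal(nrow(camp$image_truth), 30 * 15)   # 450 SPI frames
  expect_equal(nlevels(droplevels(camp$stations$group)), 3)
  expect_equal(range(camp$stations$pressure), c(0, 3.26))
  # all-zero pressure -> everything Control
  camp0 <- generate_campaign(
    gradient_spec(n_stations = 4, pressure_values = rep(0, 4), seed = 2),
    with_tracks = FALSE)
  expect_true(all(camp0$stations$group == "Control"))
})

test_that("a flat campaign (no effect, no noise) gives degenerate tests", {
  spec <- gradient_spec(
    n_stations = 6, images_per_station = 3,
    pressure_values = c(0, 0.05, 0.8, 1.2, 2.8, 3.2),
    response = list(ratio = c(a = 0, b = 0, c = 10),
                    penetration = c(intercept = 14, slope = 0),
                    rugosity = c(a = 0, b = 0, c = 2),
                    interstice = c(a = 0, b = 0, c = 0.2),
                    perimeter = c(intercept = 500, slope = 0),
                    solidity = c(intercept = 0.7, slope = 0)),
    noise_sd = list(ratio = 0, penetration = 0, rugosity = 0, interstice = 0,
                    perimeter = 0, solidity = 0),
    thalli_stations = 2, seed = 9)
  camp <- generate_campaign(spec, with_tracks = FALSE)
  st <- aggregate(ratio ~ station, camp$image_truth, mean)
  st <- merge(st, camp$stations)
  pm <- permanova_oneway(st$ratio, st$group)
  expect_true(pm$degenerate)
  expect_equal(pm$p_value, 1)
})

test_that("a no-effect campaign with noise is rarely significant", {
  spec0 <- function(s) gradient_spec(
    n_stations = 9, images_per_station = 4,
    pressure_values = c(0, 0.03, 0.06, 0.8, 1.1, 1.4, 2.6, 2.9, 3.2),
    response = list(ratio = c(a = 0, b = 0, c = 10),
                    penetration = c(intercept = 14, slope = 0),
                    rugosity = c(a = 0, b = 0, c = 2),
                    interstice = c(a = 0, b = 0, c = 0.2),
                    perimeter = c(intercept = 500, slope = 0),
                    solidity = c(intercept = 0.7, slope = 0)),
    thalli_stations = 2, seed = s)
  sig <- vapply(1:20, function(s) {
    camp <- generate_campaign(spec0(s), with_tracks = FALSE)
    st <- aggregate(ratio ~ station, camp$image_truth, mean)
    st <- merge(st, camp$stations)
    permanova_oneway(st$ratio, st$group, n_permutations = 199,
                     seed = s, pairwise = FALSE)$p_value <= 0.05
  }, TRUE)
  expect_lte(sum(sig), 1)  # about the nominal 5% of 20 seeds
})
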