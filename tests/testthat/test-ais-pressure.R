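make_pings <- function(speeds, spacing = 25, vessel = "V1", season = "s1",
                       y = 10) {
  n <- length(speeds)
  data.frame(vessel_id = vessel, timestamp = seq_len(n) * 10,
             x = (seq_len(n) - 1) * spacing, y = y, speed = speeds,
             season = season, in_fleet = TRUE)
}

test_that("maximal in-window runs become segments with chord lengths", {
  segs <- detect_dredging_segments(make_pings(rep(3.5, 5)))
  expect_equal(length(unique(segs$segment_id)), 1)
  expect_equal(segment_lengths(segs)$length_m, 100)

  # an out-of-window ping splits the run
  segs2 <- detect_dredging_segments(make_pings(c(3, 3, 6, 3, 3)))
  sl <- segment_lengths(segs2)
  expect_equal(nrow(sl), 2)
  expect_equal(sl$length_m, c(25, 25))

  # isolated in-window pings give no segment
  expect_equal(nrow(detect_dredging_segments(make_pings(c(6, 3, 6)))), 0)
})

test_that("season changes, fleet flags and ordering are honoured", {
  p <- make_pings(rep(3.5, 4))
  p$season <- c("s1", "s1", "s2", "s2")
  sl <- segment_lengths(detect_dredging_segments(p))
  expect_equal(nrow(sl), 2)  # never bridge seasons

  p2 <- make_pings(rep(3.5, 4))
  p2$in_fleet <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(nrow(segment_lengths(detect_dredging_segments(p2))), 1)

  bad <- make_pings(rep(3.5, 3))
  bad$timestamp <- c(3, 2, 1)
  expect_error(detect_dredging_segments(bad), "ordered")
})

test_that("rasterized swept area follows length-times-width with clipping", {
  grid <- define_grid(c(0, 0), 50, 2, 2)
  seg1 <- data.frame(segment_id = 1, season = "s1", x = c(0, 50), y = c(25, 25))
  sw <- rasterize_swept_area(seg1, grid)
  expect_equal(sw$swept_m2, 75)

  seg2 <- data.frame(segment_id = 1, season = "s1", x = c(0, 100), y = c(25, 25))
  sw2 <- rasterize_swept_area(seg2, grid)
  expect_equal(sw2$swept_m2, c(75, 75))
  expect_equal(sw2$col, c(1L, 2L))

  seg0 <- data.frame(segment_id = 1, season = "s1", x = c(10, 10), y = c(5, 5))
  expect_equal(nrow(rasterize_swept_area(seg0, grid)), 0)

  outside <- data.frame(segment_id = 1, season = "s1", x = c(-10, 10),
                        y = c(5, 5))
  expect_error(rasterize_swept_area(outside, grid), "outside")
  expect_equal(sum(rasterize_swept_area(outside, grid, clip = TRUE)$swept_m2),
               10 * 1.5)
})

test_that("swept area is conserved over random polylines", {
  grid <- define_grid(c(0, 0), 50, 10, 10)
  set.seed(404)
  for (i in 1:20) {
    n_vert <- sample(2:5, 1)
    seg <- data.frame(segment_id = 1, season = "s1",
                      x = runif(n_vert, 1, 499), y = runif(n_vert, 1, 499))
    len <- sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
    sw <- rasterize_swept_area(seg, grid)
    expect_lt(abs(sum(sw$swept_m2) - len * 1.5), 1e-6)
  }
})

test_that("pressure cumulation divides by the cell area across seasons", {
  grid <- define_grid(c(0, 0), 50, 1, 1)
  one <- data.frame(season = "s1", row = 1L, col = 1L, swept_m2 = 2500)
  expect_equal(cumulate_pressure(one, grid)$pressure[1, 1], 1.0)

  five <- data.frame(season = paste0("s", 1:5), row = 1L, col = 1L,
                     swept_m2 = 2350)
  expect_equal(cumulate_pressure(five, grid)$pressure[1, 1], 4.7)

  empty <- data.frame(season = character(), row = integer(), col = integer(),
                      swept_m2 = numeric())
  expect_true(all(cumulate_pressure(empty, grid, seasons = "s1")$pressure == 0))
  expect_warning(cumulate_pressure(one, grid, seasons = c("s1", "s2")),
                 "zero layers")
})

test_that("group assignment reproduces the observed group ranges", {
  expect_equal(as.character(assign_groups(c(0, 0.06))),
               c("Control", "Control"))
  expect_equal(as.character(assign_groups(c(0.61, 1.0, 1.56))),
               rep("Moderate", 3))
  expect_equal(as.character(assign_groups(c(2.52, 3.26))), rep("High", 2))
  expect_error(assign_groups(-0.1), "negative")
  expect_error(assign_groups(1, thresholds = c(2, 1)))
})

test_that("widening the speed window never decreases any cell's pressure", {
  set.seed(77)
  grid <- define_grid(c(0, 0), 50, 6, 6)
  pings <- data.frame(vessel_id = "V1", timestamp = 1:60,
                      x = cumsum(runif(60, 5, 20)) %% 290,
                      y = cumsum(runif(60, -15, 15)) %% 290,
                      speed = runif(60, 0, 8), season = "s1", in_fleet = TRUE)
  press_for <- function(win) {
    segs <- detect_dredging_segments(pings, speed_window = win)
    if (!nrow(segs)) return(matrix(0, 6, 6))
    cumulate_pressure(rasterize_swept_area(segs, grid, clip = TRUE),
                      grid)$pressure
  }
  narrow <- press_for(c(2.5, 5))
  wide <- press_for(c(1.5, 6.5))
  expect_true(all(wide - narrow >= -1e-12))
})

test_that("recovered per-cell pressure matches the generator truth", {
  grid <- define_grid(c(0, 0), 50, 4, 4)
  set.seed(15)
  passes <- do.call(rbind, lapply(1:12, function(i)
    make_pass(i, "V1", sample(paste0("s", 1:3), 1),
              speed_kn = sample(c(3.1, 4.2, 6.5), 1),
              from = runif(2, 5, 195), to = runif(2, 5, 195))))
  tr <- generate_ais_tracks(passes, grid)
  segs <- detect_dredging_segments(tr$pings)
  rec <- cumulate_pressure(rasterize_swept_area(segs, grid), grid)
  tru <- cumulate_pressure(tr$truth, grid, seasons = rec$seasons)
  denom <- pmax(tru$pressure, 1e-12)
  expect_lt(max(abs(rec$pressure - tru$pressure) / denom), 1e-9)
})
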