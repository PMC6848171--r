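test_that("station aggregation computes sample means/SDs and exclusions", {
  im <- data.frame(station = rep(c("A", "B"), each = 2),
                   rugosity = c(2, 4, 1, 1),
                   penetration_cm = c(10, 12, 8, 8),
                   live_dead_ratio = c(3, NA, 2, 2),
                   ratio_defined = c(TRUE, FALSE, TRUE, TRUE))
  pro <- expand.grid(station = c("A", "B"), image = c("i1", "i2"),
                     depth_from_cm = seq(0, 9.5, by = 0.5))
  pro$pct_live <- 50; pro$pct_dead <- 30; pro$pct_interstice <- 20
  st <- data.frame(station = c("A", "B"), pressure = c(0, 3))
  ss <- aggregate_stations(im, pro, st)
  a <- ss$metrics[ss$metrics$station == "A", ]
  expect_equal(a$rugosity_mean, 3)
  expect_equal(a$rugosity_sd, sqrt(2))
  expect_equal(a$ratio_mean, 3)        # undefined image excluded
  expect_true(is.na(a$ratio_sd))       # only one defined ratio left
  expect_equal(a$n_ratio_excluded, 1L)
  b <- ss$metrics[ss$metrics$station == "B", ]
  expect_equal(b$rugosity_sd, 0)
  expect_equal(dim(ss$profiles$mean$live), c(2, 20))  # 20 bins over 0-10 cm
  expect_true(all(ss$profiles$mean$live == 50))
})

test_that("univariate pseudo-F equals the classical one-way ANOVA F", {
  pm <- permanova_oneway(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(pm$statistic, 13.5)
  expect_equal(pm$p_value, 2 / 20)  # exhaustive: all 20 splits
  expect_true(pm$exhaustive)

  set.seed(8)
  y <- rnorm(24)
  g <- rep(letters[1:3], each = 8)
  pm2 <- permanova_oneway(y, g, n_permutations = 49, seed = 1)
  f_classic <- anova(lm(y ~ g))[["F value"]][1]
  expect_equal(pm2$statistic, f_classic, tolerance = 1e-10)
})

test_that("multivariate pseudo-F matches the independent vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  y <- matrix(rnorm(60), 20, 3)
  y[1:7, ] <- y[1:7, ] + 1
  g <- rep(c("a", "b", "c"), c(7, 6, 7))
  pm <- permanova_oneway(y, g, n_permutations = 99, seed = 1)
  ad <- vegan::adonis2(dist(y) ~ g, permutations = 99)
  expect_equal(pm$statistic, ad$F[1], tolerance = 1e-8)
  expect_equal(unname(pm$ss[["total"]]), ad$SumOfSqs[3], tolerance = 1e-8)
})

test_that("permutation p-values are deterministic given a seed and valid", {
  set.seed(30)
  y <- rnorm(15)
  g <- rep(c("a", "b", "c"), each = 5)
  p1 <- permanova_oneway(y, g, n_permutations = 199, seed = 42,
                         exhaustive_limit = 10)$p_value
  p2 <- permanova_oneway(y, g, n_permutations = 199, seed = 42,
                         exhaustive_limit = 10)$p_value
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 200)
  expect_lte(p1, 1)
})

test_that("pseudo-F is invariant to shifting and equivariant to scaling", {
  set.seed(9)
  y <- matrix(rnorm(30), 15, 2)
  g <- rep(c("a", "b", "c"), each = 5)
  f0 <- permanova_oneway(y, g, pairwise = FALSE, n_permutations = 19,
                         seed = 1, exhaustive_limit = 10)
  f1 <- permanova_oneway(y + 100, g, pairwise = FALSE, n_permutations = 19,
                         seed = 1, exhaustive_limit = 10)
  f2 <- permanova_oneway(y * 3, g, pairwise = FALSE, n_permutations = 19,
                         seed = 1, exhaustive_limit = 10)
  expect_equal(f1$statistic, f0$statistic, tolerance = 1e-10)
  expect_equal(f2$statistic, f0$statistic, tolerance = 1e-10)  # F is scale-free
  expect_equal(f2$ss[["total"]], 9 * f0$ss[["total"]], tolerance = 1e-10)
})

test_that("group-of-one and single-group designs are rejected", {
  expect_error(permanova_oneway(1:5, c("a", "a", "a", "a", "b")), "size 1")
  expect_error(permanova_oneway(1:5, rep("a", 5)), "two groups")
  expect_error(permdisp(1:5, c("a", "a", "a", "a", "b")), "size 1")
})

test_that("pairwise tests report the pseudo-t convention", {
  set.seed(4)
  y <- c(rnorm(5), rnorm(5, 3), rnorm(5, 6))
  g <- rep(c("a", "b", "c"), each = 5)
  pm <- permanova_oneway(y, g, n_permutations = 99, seed = 2)
  expect_equal(nrow(pm$pairwise), 3)
  expect_equal(pm$pairwise$pseudo_t, sqrt(pm$pairwise$pseudo_F))
  bon <- permanova_oneway(y, g, n_permutations = 99, seed = 2,
                          p_adjust_method = "bonferroni")
  expect_true(all(bon$pairwise$p_adjusted >= bon$pairwise$p - 1e-12))
})

test_that("permdisp reproduces the hand-computed centroid distances", {
  pd <- permdisp(c(0, 10, 4.9, 5.1), c("A", "A", "B", "B"))
  expect_equal(unname(pd$distances), c(5, 5, 0.1, 0.1))
  expect_equal(unname(pd$group_means), c(5, 0.1))
  # zero within-group spread of distances: F is infinite (perfect separation)
  expect_true(is.infinite(pd$statistic) || pd$statistic > 1e3)

  same <- permdisp(rep(2, 6), rep(c("a", "b"), 3))
  expect_true(same$degenerate)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("permdisp F agrees with the independent vegan betadisper", {
  skip_if_not_installed("vegan")
  set.seed(19)
  y <- matrix(rnorm(40), 20, 2)
  y[11:20, ] <- y[11:20, ] * 3
  g <- rep(c("a", "b"), each = 10)
  pd <- permdisp(y, g, n_permutations = 99, seed = 1)
  bd <- vegan::betadisper(dist(y), g, type = "centroid")
  f_ref <- anova(bd)[["F value"]][1]
  expect_equal(pd$statistic, f_ref, tolerance = 1e-8)
})

test_that("normalization centers, scales, and drops constant columns", {
  set.seed(3)
  m <- cbind(a = rnorm(6), b = rnorm(6) * 10, c = rep(4, 6))
  expect_warning(nm <- normalize_profiles(m), "zero-variance")
  expect_equal(ncol(nm), 2)
  expect_equal(attr(nm, "dropped"), "c")
  expect_true(all(abs(colMeans(nm)) < 1e-12))
  expect_true(all(abs(apply(nm, 2, sd) - 1) < 1e-12))
  # two stations, n-1 scaling: deviations +/-1 over SD sqrt(2) -> +/- 1/sqrt(2)
  two <- normalize_profiles(cbind(x = c(1, 3)))
  expect_equal(sort(as.numeric(two)), c(-1, 1) / sqrt(2))
})

test_that("response fits recover noiseless parameters exactly", {
  x <- seq(0, 3.3, length.out = 20)
  f <- fit_pressure_response(x, 3 * exp(-0.8 * x) + 1, "exp_decay")
  expect_lt(max(abs(coef(f) - c(a = 3, b = 0.8, c = 1))), 1e-6)
  expect_true(f$converged)

  fl <- fit_pressure_response(x, 2 - 0.5 * x, "linear")
  expect_equal(unname(coef(fl)), c(2, -0.5), tolerance = 1e-10)
  expect_equal(predict(fl, 2), 1, tolerance = 1e-10)
  expect_equal(length(residuals(fl)), 20)
})

test_that("model selection prefers the generating family", {
  x <- seq(0, 3.3, length.out = 20)
  cmp_lin <- compare_response_families(x, 2 - 0.5 * x, seed = 1)
  expect_equal(cmp_lin$family[1], "linear")
  cmp_dec <- compare_response_families(x, 5 * exp(-1.2 * x) + 0.4, seed = 1)
  expect_equal(cmp_dec$family[1], "exp_decay")
})

test_that("a zero-rate decay is flagged as degenerate", {
  x <- seq(0, 3, length.out = 12)
  set.seed(2)
  f <- fit_pressure_response(x, rep(2, 12) + rnorm(12, 0, 1e-9), "exp_decay",
                             seed = 1)
  expect_true(f$degenerate || abs(coef(f)[["b"]]) < 1e-4)
})
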