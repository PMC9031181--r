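test_that("traditional baseline matches the worked competition example", {
  grn <- tibble::tibble(id = "g", lon = 0, lat = 0, area_m2 = 10000)
  one <- tibble::tibble(id = "a", lon = 0, lat = 0, households = 100)
  # single community: baseline and 2SFCA coincide, ratio 1
  expect_equal(traditional_accessibility(one, grn, 1000, "euclidean"), 100)
  f1 <- two_step_fca(one, grn, 1000, "euclidean")
  expect_equal(f1$A, 100)
  expect_equal(city_ratio(f1, 100)$ratio, 1)

  # second community halves 2SFCA but not the demand-blind baseline
  two <- rbind(one, tibble::tibble(id = "b", lon = 0, lat = 0, households = 100))
  at <- traditional_accessibility(two, grn, 1000, "euclidean")
  expect_equal(at, c(100, 100))
  f2 <- two_step_fca(two, grn, 1000, "euclidean")
  expect_equal(f2$A, c(50, 50))
  expect_equal(city_ratio(f2, at)$ratio, 0.5)

  # out of range -> 0; decayed-supply variant drops the household divisor
  far <- tibble::tibble(id = "far", lon = 99999, lat = 0, households = 10)
  expect_equal(traditional_accessibility(far, grn, 1000, "euclidean"), 0)
  expect_equal(
    traditional_accessibility(two, grn, 1000, "euclidean", "decayed_supply"),
    c(10000, 10000))
})

test_that("lone communities: baseline equals 2SFCA at co-location, never exceeds it", {
  set.seed(404)
  for (rep in 1:25) {
    k <- sample(1:8, 1)  # isolated clusters, one community each
    centers <- 1e6 * seq_len(k)
    com <- tibble::tibble(
      id = sprintf("c%d", seq_len(k)), lon = centers, lat = 0,
      households = sample(1:2000, k, replace = TRUE))
    # spots co-located with their community: kernel weight 1, exact identity
    grn0 <- do.call(rbind, lapply(seq_len(k), function(i) {
      m <- sample(1:5, 1)
      tibble::tibble(id = sprintf("g%d_%d", i, seq_len(m)),
                     lon = centers[i], lat = 0,
                     area_m2 = runif(m, 1e4, 3e5))
    }))
    d0 <- sample(c(2500, 5000, 10000), 1)
    f0 <- two_step_fca(com, grn0, d0, "euclidean")
    at0 <- traditional_accessibility(com, grn0, d0, "euclidean")
    expect_equal(f0$A, at0, tolerance = 1e-12)
    expect_equal(city_ratio(f0, at0)$ratio, 1, tolerance = 1e-12)

    # spread-out spots: the kernel cancels inside 2SFCA but not in the
    # demand-blind baseline, so a lone community's 2SFCA score dominates
    grn1 <- transform(grn0, lon = lon + runif(nrow(grn0), -2000, 2000),
                      lat = runif(nrow(grn0), 0, 2000))
    f1 <- two_step_fca(com, grn1, d0, "euclidean")
    at1 <- traditional_accessibility(com, grn1, d0, "euclidean")
    expect_true(all(f1$A >= at1 - 1e-12))
  }
})

test_that("ratio is invariant to uniform supply scaling", {
  set.seed(55)
  inst <- random_instance(40, 8)
  f <- two_step_fca(inst$com, inst$grn, 2500, "euclidean")
  at <- traditional_accessibility(inst$com, inst$grn, 2500, "euclidean")
  r1 <- city_ratio(f, at)$ratio
  grn2 <- transform(inst$grn, area_m2 = area_m2 * 7.3)
  f2 <- two_step_fca(inst$com, grn2, 2500, "euclidean")
  at2 <- traditional_accessibility(inst$com, grn2, 2500, "euclidean")
  expect_equal(city_ratio(f2, at2)$ratio, r1, tolerance = 1e-12)
})

test_that("Welch t-test matches the closed-form computation", {
  a <- c(1, 2, 3)
  same <- welch_t_test(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  b <- a + 10
  shifted <- welch_t_test(a, b)
  # closed form: t = -10 / sqrt(1/3 + 1/3), df = 4 (equal variances, equal n)
  expect_equal(shifted$t, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(shifted$df, 4, tolerance = 1e-9)
  expect_equal(shifted$p_value,
               2 * pt(abs(-10 / sqrt(2 / 3)), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(shifted$p_value, 0.01)
  expect_equal(shifted$stars, "***")

  # swapping groups negates t, keeps p
  rev <- welch_t_test(b, a)
  expect_equal(rev$t, -shifted$t)
  expect_equal(rev$p_value, shifted$p_value)
  expect_error(welch_t_test(1, a), "at least 2")
})

test_that("price tiers follow the contiguous closed bands", {
  expect_equal(price_tiers(c(5500, 5501, 6000, 7640, 11038, 11039, 23902,
                             23903, 100000)),
               c(1L, 2L, 2L, 2L, 3L, 4L, 4L, 5L, 5L))
  expect_warning(
    t_out <- price_tiers(c(100, 3e5), bounds = c(500, 194667)), "outside")
  expect_equal(t_out, c(1L, 5L))
  # quantile mode: 10 cities -> five tiers of 2
  expect_equal(as.vector(table(price_tiers(1:10 * 1000, mode = "quantile"))),
               rep(2L, 5))
  expect_error(price_tiers(1, breakpoints = c(2, 1)), "ascending")
})

test_that("tier OLS recovers exact and closed-form fits", {
  x <- c(1, 2, 3, 4, 5)
  fit <- tier_ols(2 * x + 1, x, rep(1L, 5))
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)

  flat <- tier_ols(rep(0.4, 5), x, rep(1L, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  set.seed(9)
  y <- 0.3 + 0.02 * x + rnorm(5, 0, 0.01)
  hand_slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit2 <- tier_ols(y, x, rep(1L, 5))
  expect_equal(fit2$slope, hand_slope, tolerance = 1e-12)
  # slope equivariance under x scaling
  fit3 <- tier_ols(y, 100 * x, rep(1L, 5))
  expect_equal(fit3$slope, hand_slope / 100, tolerance = 1e-12)

  # degenerate tiers flagged, not fitted
  deg <- tier_ols(y, rep(2, 5), rep(1L, 5))
  expect_false(deg$fitted)
  small <- tier_ols(y[1:2], x[1:2], rep(1L, 2))
  expect_false(small$fitted)
})
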