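test_that("gaussian decay has the exact boundary behavior and midpoint value", {
  for (d0 in c(1000, 2500, 5000, 10000)) {
    expect_identical(gaussian_decay(0, d0), 1)
    expect_identical(gaussian_decay(d0, d0), 0)
    expect_identical(gaussian_decay(d0 * 1.0001, d0), 0)
    expect_identical(gaussian_decay(d0 * 10, d0), 0)
    # frozen from the closed form (e^{-1/8} - e^{-1/2}) / (1 - e^{-1/2})
    expect_equal(gaussian_decay(d0 / 2, d0), 0.701366573239, tolerance = 1e-9)
  }
  g <- gaussian_decay(seq(0, 3000, by = 10), 2500)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g[1:251]) < 0))  # strictly decreasing inside the catchment
  expect_error(gaussian_decay(100, -1), "d0")
  expect_error(gaussian_decay(-5, 100), "nonnegative")
})

test_that("supply-demand ratio matches hand computation and flags unused spots", {
  com <- tibble::tibble(id = c("a", "b"), lon = c(0, 0), lat = c(0, 0),
                        households = c(100, 100))
  grn <- tibble::tibble(id = "g", lon = 0, lat = 0, area_m2 = 10000)
  dm <- pairwise_distances(com, grn, "euclidean")
  r <- supply_demand_ratio(dm, grn$area_m2, com$households, 1000)
  expect_equal(r$R, 50)  # 10000 / (1*100 + 1*100)
  expect_true(r$used)

  # no demand in range -> unused
  dm2 <- matrix(5000, 2, 1)
  r2 <- supply_demand_ratio(dm2, 10000, c(100, 100), 1000)
  expect_true(is.na(r2$R) && !r2$used)

  # only community sits exactly on the boundary: kernel weight 0 annihilates it
  dm3 <- matrix(1000, 1, 1)
  r3 <- supply_demand_ratio(dm3, 10000, 100, 1000)
  expect_true(is.na(r3$R) && !r3$used)
  expect_equal(accessibility(dm3, r3, 1000), 0)
})

test_that("two-step FCA reproduces the worked shared-spot example", {
  com <- tibble::tibble(id = c("a", "b"), lon = c(0, 0), lat = c(0, 0),
                        households = c(100, 100))
  grn <- tibble::tibble(id = "g", lon = 0, lat = 0, area_m2 = 10000)
  f <- two_step_fca(com, grn, 1000, "euclidean")
  expect_equal(f$A, c(50, 50))
  # conservation on the example: sum H_i A_i = S
  expect_equal(sum(f$households * f$A), 10000)

  # community out of range gets exactly zero
  com2 <- rbind(com, tibble::tibble(id = "far", lon = 50000, lat = 0,
                                    households = 10))
  f2 <- two_step_fca(com2, grn, 1000, "euclidean")
  expect_identical(f2$A[3], 0)
  expect_equal(f2$A[1:2], c(50, 50))

  # linearity: doubling every S doubles every A
  grn2 <- transform(grn, area_m2 = area_m2 * 2)
  expect_equal(two_step_fca(com, grn2, 1000, "euclidean")$A, c(100, 100))

  # disjoint blocks decompose independently
  comb <- tibble::tibble(id = c("u", "v"), lon = c(0, 1e6), lat = 0,
                         households = c(50, 80))
  grnb <- tibble::tibble(id = c("p", "q"), lon = c(100, 1e6 + 100), lat = 0,
                         area_m2 = c(2e4, 3e4))
  fb <- two_step_fca(comb, grnb, 2500, "euclidean")
  g1 <- gaussian_decay(100, 2500)
  expect_equal(fb$A, c(g1 * 2e4 / (g1 * 50), g1 * 3e4 / (g1 * 80)))
})

test_that("2SFCA is permutation invariant and conserves supply mass", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- random_instance(sample(5:200, 1), sample(2:50, 1))
    d0 <- sample(c(1000, 2500, 5000, 10000), 1)
    f <- two_step_fca(inst$com, inst$grn, d0, "euclidean")
    expect_true(all(is.finite(f$A)) && all(f$A >= 0))
    expect_true(all(is.finite(f$R[f$used])) && all(f$R[f$used] >= 0))
    # mass conservation over serving spots
    expect_equal(sum(f$households * f$A), sum(inst$grn$area_m2[f$used]),
                 tolerance = 1e-9)
    # permutation invariance: scores follow ids
    p <- sample(nrow(inst$com))
    q <- sample(nrow(inst$grn))
    fp <- two_step_fca(inst$com[p, ], inst$grn[q, ], d0, "euclidean")
    expect_equal(fp$A[order(p)], f$A, tolerance = 1e-12)
  }
})

test_that("vectorized 2SFCA equals the literal double-loop transcription", {
  set.seed(202)
  for (rep in 1:50) {
    inst <- random_instance(sample(2:50, 1), sample(1:10, 1), extent = 6000)
    d0 <- sample(c(1000, 2500, 5000), 1)
    f <- two_step_fca(inst$com, inst$grn, d0, "euclidean")
    o <- oracle_two_step_fca(inst$com, inst$grn, d0)
    expect_equal(f$A, o$A, tolerance = 1e-12)
    expect_equal(f$R, o$R, tolerance = 1e-12)
  }
})

test_that("degenerate supply/demand edges are handled per contract", {
  com <- tibble::tibble(id = "a", lon = 0, lat = 0, households = 10)
  expect_error(two_step_fca(com[0, ], com, 1000, "euclidean"), "demand")
  grn0 <- tibble::tibble(id = character(), lon = numeric(), lat = numeric(),
                         area_m2 = numeric())
  expect_warning(f0 <- two_step_fca(com, grn0, 1000, "euclidean"), "supply")
  expect_identical(f0$A, 0)
})
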