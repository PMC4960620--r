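test_that("cumulative rate matches its closed form and inverts exactly", {
  p <- ref_params()
  expect_identical(cumulative_rate(p, 0), 0)
  # (0.13/0.03) * (e^0.3 - 1), evaluated independently
  expect_equal(cumulative_rate(p, 10), 1.5160548, tolerance = 1e-7)
  u <- c(0, 0.1, 1, 5, 40)
  expect_equal(cumulative_rate(p, inverse_cumulative_rate(p, u)), u,
               tolerance = 1e-10)
  t <- c(0.5, 3, 60)
  expect_true(all(diff(cumulative_rate(p, t)) > 0))
  expect_error(cumulative_rate(p, -1), "non-negative")

  # homogeneous limit: R(t) -> k_m V_b t
  p0 <- model_params(1, 0, burst_geometric(5), 65, 2)
  expect_equal(cumulative_rate(p0, 3), 6)
  p_eps <- model_params(1, 1e-12, burst_geometric(5), 65, 2)
  expect_equal(cumulative_rate(p_eps, 3), 6, tolerance = 1e-9)
})

test_that("burst-count pmf handles degenerate and forced cases", {
  one <- burst_count_pmf(1, burst_deterministic(1))
  expect_equal(one$prob[one$n == 1], 1)
  expect_equal(one$tail_mass, 0)

  forced <- burst_count_pmf(3, burst_deterministic(1))
  expect_equal(forced$prob, c(0, 0, 1))

  expect_error(burst_count_pmf(0, burst_deterministic(1)), "positive integer")
  expect_error(burst_tabulated(0, 1), "mass at 0")
})

test_that("burst-count pmf equals the exhaustive convolution oracle", {
  # frozen oracle values for X = 2, shifted geometric with mean 2:
  # two bursts of size >= 1 always reach 2, so P(N=1) = P(N=2) = 1/2
  g2 <- burst_count_pmf(2, burst_geometric(2))
  expect_equal(g2$prob[1:2], c(0.5, 0.5), tolerance = 1e-12)
  expect_lt(sum(g2$prob[-(1:2)]), 1e-12)

  laws <- list(
    list(size = 3L, prob = 1),
    list(size = 1:4, prob = rep(0.25, 4)),
    list(size = c(0L, 1L, 2L, 5L), prob = c(0.3, 0.4, 0.2, 0.1)),
    list(size = c(1L, 8L), prob = c(0.9, 0.1)))
  for (X in c(1L, 5L, 12L, 20L)) for (law in laws) {
    pmf <- burst_count_pmf(X, burst_tabulated(law$size, law$prob), n_max = 12L)
    expect_equal(pmf$prob, oracle_burst_count(X, law$size, law$prob, 12L),
                 tolerance = 1e-12)
  }

  # geometric closed forms (both supports) against the same oracle applied
  # to a finely truncated tabulated copy of the law
  for (supp in c("shifted", "nonnegative")) {
    tg <- truncated_geometric(3, supp, kmax = 200L)
    pmf <- burst_count_pmf(10, burst_geometric(3, supp), n_max = 12L)
    expect_equal(pmf$prob, oracle_burst_count(10L, tg$size, tg$prob, 12L),
                 tolerance = 1e-10)
  }
})

test_that("burst-count pmf is normalized within its tail bound", {
  for (law in list(burst_geometric(5), burst_geometric(2, "nonnegative"),
                   burst_tabulated(c(0, 2, 3), c(0.2, 0.5, 0.3)))) {
    pmf <- burst_count_pmf(37, law)
    expect_true(all(pmf$prob >= 0))
    expect_equal(sum(pmf$prob) + pmf$tail_mass, 1, tolerance = 1e-12)
    expect_lte(pmf$tail_mass, 1e-10)
  }
})

test_that("division hazards: sharp threshold and its soft limit", {
  expect_equal(division_hazard(hazard_sharp(65), 64), 0)
  expect_equal(division_hazard(hazard_sharp(65), 65), Inf)
  expect_equal(division_hazard(hazard_soft(65, 4, 1), 0), 0)
  x <- 0:130
  h <- division_hazard(hazard_soft(65, 4, 1), x)
  expect_true(all(diff(h) >= 0))
  # pointwise convergence to the sharp hazard away from x = X
  hs <- division_hazard(hazard_soft(65, 1e6, 1), c(40, 64, 66, 100))
  expect_equal(hs[1:2], c(0, 0), tolerance = 1e-100)
  expect_gt(hs[3], 1e6)
  expect_error(division_hazard(hazard_sharp(65), -1), "non-negative")
})
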