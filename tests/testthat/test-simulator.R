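test_that("single-burst model yields exponential added volumes", {
  p <- model_params(0.13, 0.03, burst_deterministic(1), 1, 1)
  set.seed(11)
  s <- sample_cycles(p, 50000)
  mu <- 0.03 / 0.13                       # 1/lambda
  expect_lt(abs(mean(s$delta_V) - mu), 3 * sd(s$delta_V) / sqrt(50000))
  expect_true(all(s$n_bursts == 1L))
})

test_that("carryover one molecule short of threshold forces one burst", {
  p <- ref_params()
  set.seed(12)
  s <- sample_cycles(p, 200, carryover = p$X - 1L)
  expect_true(all(s$n_bursts == 1L))
  expect_true(all(s$final_count >= p$X))
  expect_error(sample_cycles(p, 5, carryover = p$X), "below")
})

test_that("smaller newborns take longer to reach the threshold", {
  p <- model_params(0.13, 0.03, burst_geometric(5), 50, 1)
  set.seed(13)
  means <- vapply(c(1, 2, 4), function(vb)
    mean(sample_cycles(p, 4000, V_b = vb)$fpt), numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("conditional on the burst count the added volume is Gamma", {
  # deterministic bursts of 1 with X = n pin N = n exactly
  p <- model_params(0.13, 0.03, burst_deterministic(1), 12, 1)
  set.seed(14)
  s <- sample_cycles(p, 10000)
  ks <- suppressWarnings(ks.test(s$delta_V, pgamma, shape = 12,
                                 rate = 0.13 / 0.03))
  expect_gt(ks$p.value, 0.01)
})

test_that("records conserve exponential growth and are seed-deterministic", {
  p <- ref_params()
  set.seed(15)
  s <- sample_cycles(p, 2000)
  expect_equal(s$V_d, s$V_b * exp(p$alpha * s$fpt), tolerance = 1e-12)
  expect_equal(s$V_d, s$V_b + s$delta_V, tolerance = 1e-12)
  for (mech in list(mechanism_baseline(), mechanism_saturating_rate(5),
                    mechanism_soft_threshold(4, 1))) {
    set.seed(16); a <- sample_cycles(p, 300, mech)
    set.seed(16); b <- sample_cycles(p, 300, mech)
    expect_identical(a, b)
  }
})

test_that("a very steep soft threshold reproduces the sharp-threshold adder", {
  p <- ref_params()
  set.seed(17)
  sharp <- sample_cycles(p, 15000)$delta_V
  soft <- sample_cycles(p, 15000, mechanism_soft_threshold(H = 1e6, c = 1))$delta_V
  expect_lt(abs(mean(soft) - mean(sharp)) / mean(sharp), 0.02)
  cv2 <- function(x) var(x) / mean(x)^2
  expect_lt(abs(cv2(soft) - cv2(sharp)) / cv2(sharp), 0.05)
})

test_that("thinning reproduces the saturated arrival process exactly", {
  # first inter-burst gap in the added-volume coordinate has survival
  # exp(-integral of lambda/(1 + (V_b + u)/V_sat)) -- closed form below
  p <- ref_params(V_b = 2)
  V_sat <- 5
  lam <- p$k_m / p$alpha
  set.seed(18)
  gaps <- replicate(5000, {
    u <- 0
    repeat {
      u <- u + rexp(1, lam)
      if (runif(1) < 1 / (1 + (p$V_b + u) / V_sat)) break
    }
    u
  })
  surv_cdf <- function(u) {
    H <- lam * V_sat * log((V_sat + p$V_b + u) / (V_sat + p$V_b))
    1 - exp(-H)
  }
  expect_gt(suppressWarnings(ks.test(gaps, surv_cdf))$p.value, 0.01)
  # and the package's saturating mechanism slows large cells: positive trend
  set.seed(19)
  ex <- mechanism_correlation_experiment(p, mechanism_saturating_rate(V_sat),
                                         n_cells = 2000)
  expect_gt(cor(ex$records$V_b, ex$records$delta_V, method = "spearman"), 0)
})

test_that("lineages: degenerate case, stationarity at the adder fixed point", {
  p <- ref_params()
  set.seed(20); one <- sample_lineages(p, 50, 1)
  set.seed(20); ref <- sample_cycles(p, 50, carryover = rep(0L, 50))
  expect_equal(one$delta_V, ref$delta_V)
  expect_equal(one$generation, rep(1L, 50))

  set.seed(21)
  lin <- sample_lineages(p, 4000, 12)
  last <- lin[lin$generation == 12, ]
  target <- deltaV_moments(added_volume_distribution(p))$mean
  expect_lt(abs(mean(last$V_b) - target) / target, 0.03)
  # within-lineage bookkeeping: next newborn is half the division size
  l1 <- lin[lin$lineage_id == 1, ]
  expect_equal(l1$V_b[-1], l1$V_d[-nrow(l1)] / 2, tolerance = 1e-12)
})

test_that("initiation model reduces to baseline when the delay vanishes", {
  p <- ref_params()
  ip <- initiation_model_params(p, theta = 1, T_CD = 0)
  set.seed(22)
  sim <- sample_initiation_model(ip, 4000)
  base <- sample_cycles(p, 4000)$delta_V
  expect_gt(suppressWarnings(ks.test(sim$cycles$delta_V, base))$p.value, 0.01)
})

test_that("initiation queue overflow is reported, not silently mangled", {
  p <- ref_params()
  ip <- initiation_model_params(p, theta = 1, T_CD = 300)
  set.seed(23)
  expect_error(sample_initiation_model(ip, 200, max_pending = 4L),
               "outpaced")
})
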