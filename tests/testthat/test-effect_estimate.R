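test_that("standard error back-calculation from interval limits is the Wald inversion", {
  # frozen from (log(2.59) - log(0.997)) / (2 * qnorm(0.975))
  expect_equal(brown()$se, 0.2435408, tolerance = 1e-6)
  expect_equal(se_from_limits(brown()), brown()$se)

  # unit-SE symmetric interval on the identity scale
  sym <- effect_estimate(0, qnorm(0.025), qnorm(0.975), scale = "identity")
  expect_equal(sym$se, 1.0)

  # non-default level: limits built at 90% must invert with the 90% quantile
  est90 <- effect_estimate(2, exp(log(2) - qnorm(0.95) * 0.4),
                           exp(log(2) + qnorm(0.95) * 0.4),
                           level = 0.90, scale = "log")
  expect_equal(est90$se, 0.4)
})

test_that("constructor enforces the type invariants", {
  expect_error(effect_estimate(1.61, scale = "log"), "either")
  expect_error(effect_estimate(1.61, 2.0, 2.59, scale = "log"), "bracket")
  expect_error(effect_estimate(1.61, 0.997, 2.59, level = 1.2, scale = "log"),
               "level")
  expect_error(effect_estimate(-1, se = 0.2, scale = "log"), "positive")
  expect_error(effect_estimate(1.61, -0.1, 2.59, scale = "log"), "positive")
  expect_error(effect_estimate(1, se = -0.2, scale = "log"), "positive")
  # supplied SE inconsistent with limits beyond 1% relative is refused
  expect_error(effect_estimate(1.61, 0.997, 2.59, scale = "log", se = 0.3),
               "disagrees")
  # consistent SE is accepted and kept
  est <- effect_estimate(1.61, 0.997, 2.59, scale = "log", se = 0.2435)
  expect_equal(est$se, 0.2435)
})

test_that("z scores are signed standardized log-scale distances", {
  est <- brown()
  expect_equal(z_score(est, 1.61), 0)
  expect_equal(z_score(est, 1), -1.9555, tolerance = 1e-4)
  expect_equal(z_score(est, 3), 2.5555, tolerance = 1e-4)
  expect_error(z_score(est, -2), "positive")
  broken <- structure(list(point = 1, scale = "identity", se = NULL),
                      class = "effect_estimate")
  expect_error(z_score(broken, 1), "standard error")
})

test_that("two-sided P-values reproduce the worked example and the tail conventions", {
  est <- brown()
  expect_printed(p_value(est, 1), "0.0505")
  expect_printed(p_value(est, 2), "0.373")
  expect_equal(p_value(est, 1.61), 1.0)
  # two-sided p is twice the smaller one-sided p
  for (h in c(0.7, 1, 1.3, 2, 4)) {
    p2 <- p_value(est, h)
    p_lo <- p_value(est, h, sided = "lower")
    p_up <- p_value(est, h, sided = "upper")
    expect_equal(p2, 2 * min(p_lo, p_up))
    expect_equal(p_lo + p_up, 1)
  }
  # "upper" is the tail toward values above the hypothesis: a hypothesis far
  # below the point estimate leaves nearly all probability above it
  expect_gt(p_value(est, 0.5, sided = "upper"), 0.999)
})

test_that("P-values never underflow to zero for finite z", {
  far <- effect_estimate(1, se = 1e-4, scale = "identity")
  p <- p_value(far, 2)  # |z| = 1e4
  expect_gt(p, 0)
  expect_lt(p_value(far, 2, log.p = TRUE), -4e7)  # log scale stays finite
  expect_equal(p_value(far, 2, log.p = TRUE),
               log(2) + pnorm(1e4, lower.tail = FALSE, log.p = TRUE))
})

test_that("limits round-trip through the derived standard error", {
  # self-consistent Wald limits reconstruct to machine precision
  for (pt in c(0.8, 1.61, 3)) {
    est <- wald_estimate(point = pt, se = 0.25)
    q <- qnorm((1 + est$level) / 2)
    expect_equal(exp(log(est$point) - q * est$se), est$lower)
    expect_equal(exp(log(est$point) + q * est$se), est$upper)
  }
  # the printed worked-example inputs are internally rounded; the round
  # trip agrees within the slack that rounding propagates (~0.5%)
  est <- brown()
  q <- qnorm(0.975)
  expect_equal(exp(log(est$point) - q * est$se), est$lower, tolerance = 0.005)
  expect_equal(exp(log(est$point) + q * est$se), est$upper, tolerance = 0.005)
})

test_that("p is maximal at the point estimate and scale-equivariant", {
  est <- brown()
  grid <- c(0.6, 0.9, 1.2, 1.61, 2.1, 2.8, 4)
  p <- p_value(est, grid)
  expect_equal(which.max(p), which(grid == 1.61))
  # strictly decreasing with |z|
  ord <- order(abs(z_score(est, grid)))
  expect_true(all(diff(p[ord]) < 0 | diff(abs(z_score(est, grid))[ord]) == 0))
  # multiplying estimate, limits, and hypothesis by c > 0 changes nothing
  for (c0 in c(0.1, 3.7)) {
    scaled <- effect_estimate(1.61 * c0, 0.997 * c0, 2.59 * c0, scale = "log")
    expect_equal(z_score(scaled, grid * c0), z_score(est, grid))
    expect_equal(p_value(scaled, grid * c0), p_value(est, grid))
  }
})

test_that("estimates CSV reader handles limit-based and SE-based rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "label,point,lower,upper,level,scale,se",
    "limits row,1.61,0.997,2.59,0.95,log,",
    "se row,1.61,,,,log,0.2435408",
    "difference row,0.4,,,,identity,0.21"), path)
  ests <- read_estimates(path)
  expect_named(ests, c("limits row", "se row", "difference row"))
  expect_equal(ests[["limits row"]]$se, ests[["se row"]]$se, tolerance = 1e-6)
  expect_equal(ests[["difference row"]]$scale, "identity")
  # an SE-only row yields the same panel as the limits-derived fixture
  hyps <- c(0.5, 1, 2)
  expect_equal(test_panel(ests[["se row"]], hyps)$p,
               test_panel(ests[["limits row"]], hyps)$p, tolerance = 1e-6)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,point,lower,upper,level,scale,se",
               "broken,1.61,2.0,2.59,0.95,log,"), bad)
  expect_error(read_estimates(bad), "row 1")
})
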