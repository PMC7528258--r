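test_that("S-value transform and its inverse obey the log identities", {
  expect_equal(s_value(1), 0)
  expect_equal(s_value(0.5), 1)
  expect_equal(s_value(0.25), 2)
  expect_printed(s_value(0.05), "4.32")
  expect_printed(s_value(0.0001), "13.3")
  expect_equal(s_value(exp(-1), base = "nats"), 1)
  expect_equal(s_value(0.5, base = "nats"), log(2))
  # exact inverse in both bases
  p <- c(1, 0.7, 0.05, 1e-8)
  expect_equal(p_from_s(s_value(p)), p)
  expect_equal(p_from_s(s_value(p, "nats"), "nats"), p)
  expect_printed(p_from_s(10), "0.000977")  # ten heads in a row
  expect_error(s_value(0), "0, 1")
  expect_error(s_value(1.2), "0, 1")
  expect_error(p_from_s(-1), "non-negative")
})

test_that("surprisal is additive over independent P-values and bounds inversion", {
  set.seed(11)
  p1 <- runif(50); p2 <- runif(50)
  expect_equal(s_value(p1 * p2), s_value(p1) + s_value(p2))
  # more than one bit against H exactly when p < 1/2
  p <- c(0.49, 0.499, 0.5, 0.51, 0.9)
  expect_equal(s_value(p) > 1, p < 0.5)
})

test_that("MLR and deviance reproduce the reference translation table", {
  # rows: p, printed S (bits), printed MLR, printed deviance
  rows <- list(
    list(0.99,      "0.014", "1.00",   "0.00016"),
    list(0.90,      "0.15",  "1.01",   "0.016"),
    list(0.50,      "1.00",  "1.26",   "0.45"),
    list(0.25,      "2.00",  "1.94",   "1.32"),
    list(0.10,      "3.32",  "3.87",   "2.71"),
    list(0.05,      "4.32",  "6.83",   "3.84"),
    list(0.025,     "5.32",  "12.3",   "5.02"),
    list(0.01,      "6.64",  "27.6",   "6.63"),
    list(0.005,     "7.64",  "51.4",   "7.88"),
    list(0.0001,    "13.3",  "1935",   "15.1"),
    # tail cutoffs quoted as probabilities and re-inverted two-sidedly:
    # 5 and 6 sigma are upper-normal tails, genome-wide is 1 in 1e8
    list(pnorm(-5), "21.7",  "5.2e5",  "26.3"),
    list(1e-8,      "26.6",  "1.4e7",  "32.8"),
    list(pnorm(-6), "29.9",  "1.3e8",  "37.4"))
  for (r in rows) {
    expect_printed(s_value(r[[1]]), r[[2]])
    expect_printed(mlr_from_p(r[[1]]), r[[3]])
    expect_printed(deviance_from_p(r[[1]]), r[[4]])
  }
  expect_equal(mlr_from_p(1), 1)
  expect_equal(deviance_from_p(1), 0)
})

test_that("deviance, MLR, and the likelihood-ratio oracle cohere", {
  set.seed(7)
  p <- c(10^runif(40, -9, 0))
  expect_equal(deviance_from_p(p), 2 * log(mlr_from_p(p)))
  # brute-force likelihood oracle on the Wald model: the MLR is the normal
  # density at its mode over the density at the observed z
  z <- qnorm(p / 2, lower.tail = FALSE)
  expect_equal(mlr_from_p(p), dnorm(0) / dnorm(z))
  # rounded S and deviance coincide across the contentious p range
  for (pp in c(0.005, 0.01, 0.025, 0.05, 0.10)) {
    expect_identical(round(s_value(pp)), round(deviance_from_p(pp)))
  }
})

test_that("the evidential panel reproduces the worked-example reanalysis", {
  panel <- test_panel(brown(), c("halving" = 0.5, "null" = 1,
                                 "point" = 1.61, "doubling" = 2,
                                 "tripling" = 3, "quintupling" = 5))
  expect_s3_class(panel, "surprisal_panel")
  expect_equal(panel$label[1], "halving")
  printed <- list(                 #     p        s       mlr      deviance
    halving     = c("1.6e-6",  "19.3", "1.0e5", "23.1"),
    null        = c("0.0505",  "4.31", "6.77",  "3.82"),
    point       = c("1.00",    "0.00", "1.00",  "0.00"),
    doubling    = c("0.373",   "1.42", "1.49",  "0.79"),
    tripling    = c("0.01",    "6.56", "26.2",  "6.53"),
    quintupling = c("3.3e-6",  "18.2", "5.0e4", "21.7"))
  for (i in seq_len(nrow(panel))) {
    row <- printed[[panel$label[i]]]
    expect_printed(panel$p[i], row[1])
    expect_printed(panel$s_bits[i], row[2])
    expect_printed(panel$mlr[i], row[3])
    expect_printed(panel$deviance[i], row[4])
    # panel-level coherence: deviance = z^2 = 2 ln MLR
    expect_equal(panel$deviance[i], panel$z[i]^2)
    expect_equal(panel$deviance[i], 2 * log(panel$mlr[i]))
  }
  expect_error(test_panel(brown(), numeric(0)), "non-empty")
})

test_that("extreme hypotheses keep finite S-values via the log-space tail", {
  est <- effect_estimate(1, se = 0.01, scale = "identity")
  panel <- test_panel(est, 2)  # z = 100; linear p underflows
  expect_gt(panel$p, 0)
  lp <- log(2) + pnorm(100, lower.tail = FALSE, log.p = TRUE)
  expect_equal(panel$s_bits, -lp / log(2))
  expect_gt(panel$s_bits, 7000)
})

test_that("display rounding switches from two decimals to integers above 10 bits", {
  expect_identical(format_s_value(4.31), "4.31")
  expect_identical(format_s_value(19.27), "19")
  expect_identical(format_s_value(10.0), "10.00")
  expect_identical(format_s_value(c(0, 10.4)), c("0.00", "10"))
  expect_error(format_s_value(-1), "non-negative")
  # text table renders and carries the display policy
  lines <- format_panel(test_panel(brown(), c(null = 1, halving = 0.5)))
  expect_match(lines[1], "MLR")
  expect_match(lines[3], "4.31")
  expect_match(lines[4], "19")
})
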