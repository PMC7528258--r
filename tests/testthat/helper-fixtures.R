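# The worked-example estimate, rebuilt from its printed inputs each time.
brown <- function() {
  effect_estimate(1.61, 0.997, 2.59, level = 0.95, scale = "log",
                  label = "HDPS-adjusted hazard ratio")
}

# A self-consistent estimate whose limits are exact Wald limits, for
# round-trip properties that hold to machine precision.
wald_estimate <- function(point = 2, se = 0.3, level = 0.95, scale = "log") {
  tr <- if (scale == "log") log else identity
  inv <- if (scale == "log") exp else identity
  q <- qnorm((1 + level) / 2)
  effect_estimate(point, inv(tr(point) - q * se), inv(tr(point) + q * se),
                  level = level, scale = scale)
}

# Compare a computed value against a printed (rounded) one: agreement
# within half a unit in the last printed digit, capped at 3 significant
# figures. `printed` is given as the string that appears in print, so the
# precision is taken from the text, not guessed.
expect_printed <- function(actual, printed) {
  value <- as.numeric(printed)
  mantissa <- sub("[eE].*$", "", printed)
  digits <- sub("^0+", "", gsub("[^0-9]", "", mantissa))
  sf <- min(nchar(digits), 3L)
  ulp <- if (value == 0) {
    10^-nchar(sub(".*\\.", "", mantissa))
  } else {
    10^(floor(log10(abs(value))) - sf + 1)
  }
  expect_lte(abs(actual - value), 0.51 * ulp,
             label = sprintf("|%.6g - %s|", actual, printed))
}
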