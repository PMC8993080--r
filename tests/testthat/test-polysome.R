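rect_trace <- function(mono_area = 30, poly_area = 70, baseline = 0) {
  # rectangular pulses: height = area / width, on a fine grid
  pos <- seq(0, 100, by = 0.1)
  y <- rep(baseline, length(pos))
  y[pos >= 10 & pos <= 25] <- baseline + mono_area / 15
  y[pos >= 40 & pos <= 75] <- baseline + poly_area / 35
  list(trace = data.frame(position = pos, absorbance = y),
       regions = list(monosome = c(10, 25), polysome = c(40, 75)))
}

test_that("polysome percentage integrates constructed areas correctly", {
  tr <- rect_trace(30, 70)
  expect_equal(polysome_percentage(tr$trace, tr$regions), 70, tolerance = 1e-9)
  zero <- rect_trace(30, 0)
  expect_equal(polysome_percentage(zero$trace, zero$regions), 0)
  # constant baseline is subtracted before integration
  shifted <- rect_trace(30, 70, baseline = 0.5)
  expect_equal(polysome_percentage(shifted$trace, shifted$regions,
                                   baseline = 0.5), 70, tolerance = 1e-9)
  # baseline estimated from an inter-peak window
  expect_equal(polysome_percentage(shifted$trace, shifted$regions,
                                   baseline = NULL,
                                   baseline_window = c(27, 38)),
               70, tolerance = 1e-9)
  flat <- data.frame(position = 0:100, absorbance = 0)
  expect_error(polysome_percentage(flat, list(monosome = c(10, 25),
                                              polysome = c(40, 75))),
               "not positive")
})

test_that("spike normalization is the efficiency-corrected abundance ratio", {
  expect_equal(spike_normalized_quantity(20, 20), 1)
  expect_equal(spike_normalized_quantity(19, 20), 2)       # one doubling
  expect_equal(spike_normalized_quantity(21, 20, af = 1.9, spike_af = 2),
               1.9^-21 / 2^-20, tolerance = 1e-15)
  expect_equal(spike_normalized_quantity(Inf, 20), 0)
  expect_error(spike_normalized_quantity(20, 20, af = 1))
  expect_error(spike_normalized_quantity(20, 20, af = 2.4))
})

test_that("fraction distributions normalize and accumulate to 100", {
  u <- fraction_distribution(rep(3.7, 13))
  expect_equal(u$percentage, rep(100 / 13, 13))
  expect_equal(u$cumulative, 100 * (1:13) / 13)
  last <- fraction_distribution(c(rep(0, 12), 5))
  expect_equal(last$cumulative, c(rep(0, 12), 100))
  set.seed(4)
  for (i in 1:20) {
    fd <- fraction_distribution(runif(13, 0.01, 10))
    expect_true(all(diff(fd$cumulative) >= 0))
    expect_equal(fd$cumulative[13], 100, tolerance = 1e-9)
  }
  expect_error(fraction_distribution(rep(0, 13)))
})

test_that("association score hits its degenerate bounds and orders shifts", {
  expect_equal(area_above_cumulative(
    fraction_distribution(c(1, rep(0, 12))))$score, 0)
  expect_equal(area_above_cumulative(
    fraction_distribution(c(rep(0, 12), 1)))$score, 12 / 13)
  # scale invariance
  v <- c(1, 2, 3, 4, 5, 6, 7, 6, 5, 4, 3, 2, 1)
  expect_equal(area_above_cumulative(fraction_distribution(v))$score,
               area_above_cumulative(fraction_distribution(v * 37.5))$score,
               tolerance = 1e-12)
  # moving mass rightward strictly increases the score, 100/100 pairs
  set.seed(10)
  for (i in 1:100) {
    w <- runif(13, 0.05, 5)
    from <- sample(1:12, 1)
    to <- if (from == 12) 13L else sample((from + 1):13, 1)
    w2 <- w
    moved <- w[from] * runif(1, 0.1, 1)
    w2[from] <- w2[from] - moved
    w2[to] <- w2[to] + moved
    s1 <- area_above_cumulative(fraction_distribution(w))$score
    s2 <- area_above_cumulative(fraction_distribution(w2))$score
    expect_gt(s2, s1)
  }
})

test_that("trapezoid scoring agrees with step scoring up to the half-bin shift", {
  v <- runif(13, 0.1, 4)
  fd <- fraction_distribution(v)
  st <- area_above_cumulative(fd, "step")
  tz <- area_above_cumulative(fd, "trapezoid")
  # trapezoid averages successive cumulative values: raw difference is half
  # of the first-bin mass pattern, always within half a bin
  expect_lt(abs(st$raw_area - tz$raw_area), 0.5)
  expect_equal(tz$raw_area,
               sum(1 - (c(0, head(fd$cumulative, -1)) + fd$cumulative) / 200),
               tolerance = 1e-12)
})

test_that("condition summaries report mean and SD per condition in order", {
  sc <- data.frame(condition = rep(c("WT_control", "WT_NCS"), each = 2),
                   score = c(0.4, 0.6, 0.5, 0.5))
  out <- compare_conditions(sc)
  expect_identical(out$condition, c("WT_control", "WT_NCS"))
  expect_equal(out$mean, c(0.5, 0.5))
  expect_equal(out$sd, c(sd(c(0.4, 0.6)), 0))
  single <- compare_conditions(data.frame(condition = "x", score = 0.3))
  expect_true(is.na(single$sd))
  # 4 x 4 synthetic table matches direct recomputation
  set.seed(20)
  tab <- data.frame(condition = rep(paste0("c", 1:4), each = 4),
                    score = runif(16))
  out2 <- compare_conditions(tab)
  expect_equal(out2$mean, as.numeric(tapply(tab$score, tab$condition, mean)[
    paste0("c", 1:4)]), tolerance = 1e-12)
  expect_equal(out2$sd, as.numeric(tapply(tab$score, tab$condition, sd)[
    paste0("c", 1:4)]), tolerance = 1e-12)
})

test_that("isoform mixtures are additive on zero-noise data", {
  # two isoforms with disjoint amplicons; a synthetic "total" assay sees the
  # quantity-weighted mixture of their distributions
  w1 <- c(8, 4, 2, 1, 1, 1, 2, 3, 4, 5, 6, 7, 8)
  w2 <- c(1, 1, 1, 2, 4, 8, 10, 10, 8, 6, 4, 2, 1)
  q1 <- quantify_ct_table(simulate_fraction_cts(w1))$quantity * sum(w1)
  q2 <- quantify_ct_table(simulate_fraction_cts(w2))$quantity * sum(w2)
  total <- fraction_distribution(q1 + q2)
  direct <- fraction_distribution((w1 / sum(w1)) * sum(w1) +
                                    (w2 / sum(w2)) * sum(w2))
  expect_equal(total$percentage, direct$percentage, tolerance = 1e-9)
})
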