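test_that("delta_log2 is the antisymmetric log2 ratio with zero flagged", {
  expect_identical(delta_log2(8, 2), 2)
  expect_identical(delta_log2(5, 5), 0)
  expect_true(is.na(delta_log2(0, 5)))
  expect_true(is.na(delta_log2(5, 0)))
  x <- c(1.5, 20, 0.3); y <- c(7, 0.04, 3)
  expect_equal(delta_log2(x, y), -delta_log2(y, x))
})

test_that("OLS fit reproduces exact geometric configurations", {
  x <- c(-2, -1, 0, 1, 3)
  fit <- fit_passive_regression(data.frame(delta_mrna = x,
                                           delta_rd = -0.5 * x))
  expect_equal(fit$b, -0.5, tolerance = 1e-12)
  expect_equal(fit$a, 0, tolerance = 1e-12)
  expect_equal(fit$pearson_r, -1, tolerance = 1e-12)
  sq <- data.frame(delta_mrna = c(0, 1, 0, 1), delta_rd = c(0, 0, 1, 1))
  fit2 <- fit_passive_regression(sq)
  expect_equal(fit2$b, 0, tolerance = 1e-12)
  expect_equal(fit2$a, 0.5, tolerance = 1e-12)
  expect_equal(fit2$pearson_r, 0, tolerance = 1e-12)
  expect_error(fit_passive_regression(
    data.frame(delta_mrna = c(1, 1, 1), delta_rd = 1:3)), "degenerate")
  expect_error(fit_passive_regression(
    data.frame(delta_mrna = 1:2, delta_rd = 1:2)), "at least 3")
})

test_that("OLS fit matches lm() and ignores point order and duplication", {
  set.seed(5)
  pairs <- data.frame(delta_mrna = rnorm(300), delta_rd = rnorm(300))
  fit <- fit_passive_regression(pairs)
  ref <- lm(delta_rd ~ delta_mrna, data = pairs)
  expect_equal(fit$a, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit$b, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit$pearson_r, cor(pairs$delta_mrna, pairs$delta_rd),
               tolerance = 1e-12)
  expect_equal(fit$residual_sd, summary(ref)$sigma, tolerance = 1e-10)
  shuffled <- pairs[sample.int(300), ]
  doubled <- rbind(pairs, pairs)
  expect_equal(fit_passive_regression(shuffled)[c("a", "b", "pearson_r")],
               fit[c("a", "b", "pearson_r")], tolerance = 1e-12)
  expect_equal(fit_passive_regression(doubled)[c("a", "b", "pearson_r")],
               fit[c("a", "b", "pearson_r")], tolerance = 1e-12)
})

test_that("signed distances follow the line geometry in both modes", {
  fit <- structure(list(a = 0, b = 1), class = "passive_regression")
  p <- data.frame(delta_mrna = 0, delta_rd = 2)
  expect_equal(signed_distance(p, fit, "vertical"), 2)
  expect_equal(signed_distance(p, fit, "orthogonal"), sqrt(2))
  on_line <- data.frame(delta_mrna = 3, delta_rd = 3)
  expect_equal(signed_distance(on_line, fit, "vertical"), 0)
  expect_equal(signed_distance(on_line, fit, "orthogonal"), 0)
  # orthogonal = vertical / sqrt(1 + b^2) for random lines and points
  set.seed(8)
  for (i in 1:1000) {
    f <- structure(list(a = rnorm(1, 0, 2), b = rnorm(1, 0, 3)),
                   class = "passive_regression")
    q <- data.frame(delta_mrna = rnorm(1, 0, 4), delta_rd = rnorm(1, 0, 4))
    v <- signed_distance(q, f, "vertical")
    o <- signed_distance(q, f, "orthogonal")
    expect_equal(o, v / sqrt(1 + f$b^2), tolerance = 1e-12)
  }
})

test_that("orthogonal distance is invariant under rotation onto the x-axis", {
  set.seed(14)
  for (i in 1:20) {
    b <- rnorm(1); a <- rnorm(1)
    fit <- structure(list(a = a, b = b), class = "passive_regression")
    x <- rnorm(10); y <- rnorm(10)
    d <- signed_distance(data.frame(delta_mrna = x, delta_rd = y), fit)
    # rotate the frame by -atan(b) about (0, a): the line maps to y' = 0
    th <- atan(b)
    yp <- -sin(th) * x + cos(th) * (y - a)
    expect_equal(d, yp, tolerance = 1e-10)
  }
})

test_that("classification applies strict threshold rules per genotype", {
  expect_identical(as.character(classify_gene(1.5, 0.2)), "up_wt_only")
  expect_identical(as.character(classify_gene(0.3, 1.7)), "up_ko_only")
  expect_identical(as.character(classify_gene(1.2, 1.3)), "up_both")
  expect_identical(as.character(classify_gene(1.0, 0.0)), "none")  # strict
  expect_identical(as.character(classify_gene(-1.4, -0.1)), "down_wt_only")
  expect_identical(as.character(classify_gene(-0.2, -1.1)), "down_ko_only")
  expect_identical(as.character(classify_gene(-1.6, -2.0)), "down_both")
  expect_identical(as.character(classify_gene(NA, 1.2)), "up_ko_only")
  expect_true(attr(classify_gene(NA, 1.2), "single_genotype"))
  expect_error(classify_gene(1, 1, threshold = 0))
})

test_that("classification is monotone in the WT distance", {
  set.seed(3)
  d_ko <- runif(50, -2, 2)
  up_rank <- function(cls) ifelse(grepl("^up", cls), 1, 0)
  for (i in seq_along(d_ko)) {
    grid <- seq(-3, 3, by = 0.25)
    r <- up_rank(as.character(classify_gene(grid, rep(d_ko[i], length(grid)))))
    expect_true(all(diff(r) >= 0))  # increasing d_wt never leaves an up class
  }
})

test_that("external points project onto the fitted line as vertical residuals", {
  fit <- structure(list(a = 0, b = 0.3), class = "passive_regression")
  expect_equal(project_external_points(data.frame(x = 2, y = 1.6), fit), 1)
  expect_equal(project_external_points(data.frame(x = 2, y = 0.6), fit), 0)
  # cohort with an inflated subset recovers the offset as mean residual
  set.seed(6)
  x <- rnorm(600); y <- 0.4 * x + rnorm(600, 0, 0.2)
  boosted <- seq_len(60)
  y[boosted] <- y[boosted] + 1
  cohort_fit <- fit_passive_regression(data.frame(delta_mrna = x, delta_rd = y))
  res <- project_external_points(data.frame(x = x, y = y), cohort_fit)
  expect_equal(mean(res[boosted]) - mean(res[-boosted]), 1, tolerance = 0.1)
})

test_that("gene-list overlap uses the upper hypergeometric tail", {
  universe <- sprintf("g%05d", 1:10000)
  reference <- universe[1:116]
  classified <- c(universe[1:14], universe[200:206])  # 14 of 21 in the list
  ov <- overlap_with_gene_list(classified, reference, 10000)
  expect_identical(ov$overlap, 14L)
  expect_equal(ov$p_value, oracle_hyper_tail(14, 116, 10000, 21),
               tolerance = 1e-12)
  # classified subset of reference; disjoint sets
  allin <- overlap_with_gene_list(universe[5:9], reference, 10000)
  expect_identical(allin$overlap, 5L)
  disjoint <- overlap_with_gene_list(universe[500:520], reference, 10000)
  expect_identical(disjoint$overlap, 0L)
  expect_gt(disjoint$p_value, 0.5)
  expect_identical(overlap_with_gene_list(character(0), reference, 10000)$p_value, 1)
})
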