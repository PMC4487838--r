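test_that("bland_altman matches the direct formula", {
  p0 <- paired_measurements(c(1, 2, 3, 4), c(1, 2, 3, 4))
  ba0 <- bland_altman(p0)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)

  pc <- paired_measurements(c(5, 6, 7), c(2, 3, 4))  # constant offset 3
  bac <- bland_altman(pc)
  expect_equal(bac$mean_diff, 3)
  expect_equal(bac$sd_diff, 0)

  set.seed(21)
  x <- rnorm(40, 80, 20); y <- x + rnorm(40, -2, 6)
  ba <- bland_altman(paired_measurements(x, y))
  d <- x - y
  expect_equal(ba$mean_diff, sum(d) / 40, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 39), tolerance = 1e-12)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_error(paired_measurements(1:2, 2:3), "at least 3")
})

test_that("limits of agreement cover ~95% of normal differences", {
  set.seed(31)
  n <- 10000
  x <- rnorm(n, 100, 15)
  y <- x + rnorm(n, 1, 5)
  ba <- bland_altman(paired_measurements(x, y))
  d <- x - y
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_lt(abs(cover - 0.95), 0.01)  # ~3 binomial SDs at n = 10000
})

test_that("paired t: sentinel on zero variance, zero on antisymmetric pairs, CDF oracle", {
  ident <- paired_t(paired_measurements(c(4, 5, 6), c(4, 5, 6)))
  expect_true(is.na(ident$t) && is.na(ident$p_value))
  expect_true(ident$exact_agreement)

  anti <- paired_t(paired_measurements(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_equal(anti$t, 0, tolerance = 1e-12)
  expect_equal(anti$p_value, 1, tolerance = 1e-12)

  # frozen 5-pair oracle: t = mean(d)/(sd(d)/sqrt(n)), p from the t CDF
  tt <- paired_t(paired_measurements(c(10.1, 12.3, 9.8, 11.5, 10.9),
                                     c(9.6, 11.9, 10.4, 10.8, 10.2)))
  expect_equal(tt$t, 1.404527054112, tolerance = 1e-10)
  expect_equal(tt$p_value, 0.232851068256, tolerance = 1e-10)
})

test_that("pearson_grade applies the printed bands with closed upper ends", {
  expect_identical(pearson_grade(0), "poor")
  expect_identical(pearson_grade(0.20), "slight")
  expect_identical(pearson_grade(0.21), "fair")
  expect_identical(pearson_grade(0.5), "moderate")
  expect_identical(pearson_grade(-0.7), "good")  # graded on |r|
  expect_identical(pearson_grade(0.80), "good")
  expect_identical(pearson_grade(0.85), "excellent")
  expect_identical(pearson_grade(1), "excellent")
  expect_error(pearson_grade(1.2), "\\[-1, 1\\]")
})

test_that("ICC(2,1): perfect agreement, bias sensitivity, worked-table oracle", {
  x <- c(9, 6, 8, 7, 10, 6)
  expect_equal(icc_two_way_random(paired_measurements(x, x))$icc, 1)

  # frozen brute-force ANOVA oracle for a fixed 6 x 2 table
  res <- icc_two_way_random(paired_measurements(x, c(2, 1, 4, 1, 5, 2)))
  expect_equal(res$icc, 0.125654450261780, tolerance = 1e-12)

  # a large constant bias lowers absolute agreement but not consistency
  y <- x + 10
  agree <- icc_two_way_random(paired_measurements(x, y))$icc
  consist <- icc_two_way_random(paired_measurements(x, y),
                                type = "consistency")$icc
  expect_lt(agree, consist)
  expect_equal(consist, 1, tolerance = 1e-9)

  expect_error(icc_two_way_random(paired_measurements(c(5, 5, 5), c(5, 5, 5))),
               "between-subject")
})

test_that("ICC equals the aov-based decomposition on random tables", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    subj <- rnorm(n, 50, 12)
    m <- cbind(subj + rnorm(n, 0, 4), subj + rnorm(n, 2, 4))
    ours <- icc_two_way_random(paired_measurements(m[, 1], m[, 2]))
    df <- data.frame(y = as.vector(m), s = factor(rep(1:n, 2)),
                     r = factor(rep(1:2, each = n)))
    av <- anova(lm(y ~ s + r, df))
    msr <- av["s", "Mean Sq"]; msc <- av["r", "Mean Sq"]
    mse <- av["Residuals", "Mean Sq"]
    icc_aov <- (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
    expect_equal(ours$icc, icc_aov, tolerance = 1e-10)
    expect_equal(ours$p_value, pf(msr / mse, n - 1, n - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("increasing visit noise decreases the recovered ICC", {
  set.seed(23)
  n <- 200
  truth <- rnorm(n, 80, 15)
  iccs <- vapply(c(2, 8, 20), function(s) {
    icc_two_way_random(paired_measurements(truth + rnorm(n, 0, s),
                                           truth + rnorm(n, 0, s)))$icc
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

pb_oracle <- function(x, y) {
  # independent O(n^2) enumeration of the shifted-median slope
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (x[j] != x[i]) {
      sl <- (y[j] - y[i]) / (x[j] - x[i])
      if (sl != -1) s <- c(s, sl)
    }
  }
  s <- sort(s); N <- length(s); K <- sum(s < -1)
  b <- if (N %% 2 == 1) s[(N + 1) / 2 + K] else (s[N / 2 + K] + s[N / 2 + 1 + K]) / 2
  c(slope = b, intercept = median(y - b * x))
}

test_that("passing_bablok is exact on linear data and equals the enumeration oracle", {
  x <- 1:10
  fit <- passing_bablok(paired_measurements(x, 2 * x + 1))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  fit_id <- passing_bablok(paired_measurements(x, as.numeric(x)))
  expect_equal(fit_id$slope, 1)
  expect_equal(fit_id$intercept, 0)

  set.seed(13)
  x <- rnorm(15, 50, 10); y <- 1.1 * x - 3 + rnorm(15, 0, 4)
  fit2 <- passing_bablok(paired_measurements(x, y))
  orc <- pb_oracle(x, y)
  expect_identical(fit2$slope, unname(orc["slope"]))
  expect_identical(fit2$intercept, unname(orc["intercept"]))
  expect_true(fit2$slope_ci[1] <= fit2$slope && fit2$slope <= fit2$slope_ci[2])

  expect_error(passing_bablok(paired_measurements(c(2, 2, 2), c(1, 2, 3))),
               "all x equal")
})

test_that("SEM and SDC reproduce printed reliability rows and their identity", {
  expect_equal(round(sem(11.52, 0.80), 2), 5.15)
  expect_equal(round(sem(6.22, 0.48), 2), 4.49)
  expect_equal(sem(3, 1), 0)
  expect_equal(round(sdc(sem(11.52, 0.80)), 2), 14.28)
  expect_equal(round(sdc(sem(7.77, 0.57)), 2), 14.12)
  expect_equal(sdc(0), 0)
  expect_error(sem(5, 1.2), "<= 1")
  expect_error(sem(-1, 0.5), ">= 0")
  # sdc(sem(sd, icc)) = 1.96 sqrt(2) sd sqrt(1 - icc) for all valid inputs
  set.seed(3)
  for (i in 1:20) {
    s <- runif(1, 0, 20); r <- runif(1)
    expect_equal(sdc(sem(s, r)), 2.771858 * s * sqrt(1 - r), tolerance = 1e-6)
  }
})

test_that("reproducibility_table assembles rows and annotates failures", {
  set.seed(41)
  truth <- rnorm(22, 85, 30)
  pairs <- list(
    Vmax = paired_measurements(truth + rnorm(22, 0, 5),
                               truth + rnorm(22, -2, 5),
                               parameter = "Vmax", units = "ml"),
    LAEF = paired_measurements(rnorm(22, 46, 8), rnorm(22, 45, 8),
                               parameter = "LAEF", units = "%"),
    degenerate = paired_measurements(rep(5, 5), rep(5, 5),
                                     parameter = "degenerate")
  )
  tbl <- reproducibility_table(pairs)
  expect_s3_class(tbl, "la_agreement_table")
  expect_equal(nrow(tbl), 3)
  ok <- tbl[tbl$parameter == "Vmax", ]
  expect_true(is.finite(ok$icc) && is.finite(ok$sem) && is.finite(ok$sdc))
  expect_equal(ok$sdc, 1.96 * sqrt(2) * ok$sem, tolerance = 1e-12)
  expect_identical(pearson_grade(ok$pearson_r), ok$pearson_grade)
  bad <- tbl[tbl$parameter == "degenerate", ]
  expect_true(is.na(bad$icc))
  expect_match(bad$note, "between-subject")
  # SEM defaults to the SD of the paired differences
  expect_equal(ok$sem, ok$sd_diff * sqrt(1 - ok$icc), tolerance = 1e-12)
})
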