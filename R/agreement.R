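# Method-agreement and reliability statistics: Bland-Altman, paired t,
# graded Pearson correlation, two-way random ICC, Passing-Bablok
# regression, SEM and SDC, and the assembled reliability table.

#' Paired measurements
#'
#' Two aligned measurement vectors of the same subjects (two methods,
#' readers or visits). Pairs with missing values are dropped; at least
#' three complete pairs are required.
#'
#' @param x,y Numeric vectors of equal length.
#' @param labels Length-2 character, names of the two sources.
#' @param parameter Parameter name (e.g. `"Vmax"`).
#' @param units Measurement units (e.g. `"ml"`).
#' @return An object of class `la_paired`.
#' @export
paired_measurements <- function(x, y, labels = c("A", "B"),
                                parameter = "parameter", units = "") {
  stop_if(length(x) != length(y), "x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stop_if(length(x) < 3, "need at least 3 complete pairs")
  structure(list(x = x, y = y, labels = labels,
                 parameter = parameter, units = units, n = length(x)),
            class = "la_paired")
}

as_paired <- function(p, y = NULL, ...) {
  if (inherits(p, "la_paired")) p else paired_measurements(p, y, ...)
}

#' Bland-Altman analysis
#'
#' Differences `d = x - y`; mean difference, sample SD (n-1 denominator)
#' and 95% limits of agreement `mean +/- 1.96 * SD`.
#'
#' @param p An [paired_measurements()] (or `x` with `y` supplied).
#' @param y Optional second vector when `p` is numeric.
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(p, y = NULL) {
  p <- as_paired(p, y)
  d <- p$x - p$y
  m <- mean(d); s <- sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = p$n)
}

#' Paired two-tailed t test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom. When
#' the paired differences have zero variance the t statistic is undefined;
#' the exact-agreement sentinel (`t = NA`, `p_value = NA`,
#' `exact_agreement = TRUE` if all differences are zero) is returned
#' instead.
#'
#' @inheritParams bland_altman
#' @return List with `t`, `df`, `p_value`, `exact_agreement`.
#' @export
paired_t <- function(p, y = NULL) {
  p <- as_paired(p, y)
  d <- p$x - p$y
  if (sd(d) == 0) {
    return(list(t = NA_real_, df = p$n - 1L, p_value = NA_real_,
                exact_agreement = all(d == 0)))
  }
  tt <- t.test(p$x, p$y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, exact_agreement = FALSE)
}

#' Grade a Pearson correlation coefficient
#'
#' Ordinal grading of `|r|`: 0 poor; (0, 0.20] slight; (0.20, 0.40] fair;
#' (0.40, 0.60] moderate; (0.60, 0.80] good; (0.80, 1.00] excellent.
#' Boundaries are closed on the upper end, as conventionally printed
#' ("0.01-0.20" includes 0.20).
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Character vector of grades.
#' @examples
#' pearson_grade(c(0, 0.2, 0.85))
#' @export
pearson_grade <- function(r) {
  stop_if(any(!is.finite(r)) || any(abs(r) > 1),
          "r must lie in [-1, 1]")
  a <- abs(r)
  out <- character(length(a))
  out[a == 0] <- "poor"
  out[a > 0 & a <= 0.20] <- "slight"
  out[a > 0.20 & a <= 0.40] <- "fair"
  out[a > 0.40 & a <= 0.60] <- "moderate"
  out[a > 0.60 & a <= 0.80] <- "good"
  out[a > 0.80] <- "excellent"
  out
}

#' Two-way random intraclass correlation, ICC(2,1)
#'
#' Single-measures, absolute-agreement ICC from the two-way random-effects
#' ANOVA decomposition with n subjects and k raters:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. The p-value is
#' the upper tail of `F = MSR / MSE` with `(n - 1, (n - 1)(k - 1))`
#' degrees of freedom. The consistency form
#' `(MSR - MSE) / (MSR + (k-1) MSE)` ignores the rater (bias) variance and
#' is available via `type = "consistency"`.
#'
#' @inheritParams bland_altman
#' @param type `"agreement"` (default, ICC(2,1)) or `"consistency"`.
#' @return List with `icc`, `p_value`, `F`, `df1`, `df2`, mean squares.
#' @export
icc_two_way_random <- function(p, y = NULL, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  p <- as_paired(p, y)
  m <- cbind(p$x, p$y)
  n <- nrow(m); k <- ncol(m)
  row_m <- rowMeans(m); col_m <- colMeans(m); g <- mean(m)
  stop_if(sd(row_m) == 0, "zero between-subject variance: ICC undefined")
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  mse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2) / ((n - 1) * (k - 1))
  icc <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  Fv <- msr / mse
  list(icc = icc, p_value = pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE),
       F = Fv, df1 = n - 1, df2 = (n - 1) * (k - 1),
       msr = msr, msc = msc, mse = mse, type = type)
}

#' Passing-Bablok regression
#'
#' Non-parametric method-comparison regression (Passing & Bablok 1983).
#' All pairwise slopes `S_ij = (y_j - y_i)/(x_j - x_i)` for `i < j` are
#' formed; slopes from vertical pairs (`x_i = x_j`) are undefined and
#' excluded, slopes of exactly -1 are discarded. With `K` the number of
#' slopes below -1, the slope estimate is the median of the sorted slopes
#' shifted by `K`; the intercept is `median(y - slope * x)`. Confidence
#' bounds use the rank-based normal approximation (no bootstrap, so the
#' result is deterministic).
#'
#' @inheritParams bland_altman
#' @param conf Confidence level for the slope/intercept bounds.
#' @return List with `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `n`, `n_slopes`.
#' @examples
#' passing_bablok(paired_measurements(1:10, 2 * (1:10) + 1))
#' @export
passing_bablok <- function(p, y = NULL, conf = 0.95) {
  p <- as_paired(p, y)
  x <- p$x; yv <- p$y; n <- p$n
  stop_if(length(unique(x)) == 1, "all x equal: slope undefined")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- x[ij[, 2]] - x[ij[, 1]]
  dy <- yv[ij[, 2]] - yv[ij[, 1]]
  keep <- dx != 0
  S <- dy[keep] / dx[keep]
  S <- S[S != -1]
  N <- length(S)
  stop_if(N < 1, "fewer than one valid pairwise slope")
  S <- sort(S)
  K <- sum(S < -1)
  at <- function(idx) S[min(max(idx, 1L), N)]
  b <- if (N %% 2 == 1) {
    at((N + 1) %/% 2 + K)
  } else {
    (at(N %/% 2 + K) + at(N %/% 2 + 1 + K)) / 2
  }
  w <- qnorm(1 - (1 - conf) / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((N - w) / 2)
  m2 <- N - m1 + 1
  b_lo <- at(m1 + K); b_hi <- at(m2 + K)
  a <- median(yv - b * x)
  a_ci <- c(median(yv - b_hi * x), median(yv - b_lo * x))
  list(slope = b, intercept = a,
       slope_ci = c(b_lo, b_hi), intercept_ci = a_ci,
       n = n, n_slopes = N, conf = conf)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`. `sd` is conventionally the SD of the paired
#' (test-retest) differences; see [reproducibility_table()] for the
#' alternative pooled-SD convention.
#'
#' @param sd Standard deviation, in measurement units.
#' @param icc Intraclass correlation in `[0, 1]`.
#' @return SEM in the same units as `sd`.
#' @examples
#' sem(11.52, 0.80)  # 5.15
#' @export
sem <- function(sd, icc) {
  stop_if(any(sd < 0), "sd must be >= 0")
  stop_if(any(icc > 1), "icc must be <= 1")
  stop_if(any(icc < 0), "icc must be >= 0")
  sd * sqrt(1 - icc)
}

#' Smallest detectable change
#'
#' `SDC = 1.96 * SEM * sqrt(2)`: the smallest change exceeding the 95%
#' uncertainty of a test-retest difference.
#'
#' @param sem SEM in measurement units (>= 0).
#' @return SDC in the same units.
#' @examples
#' sdc(sem(11.52, 0.80))  # 14.28
#' @export
sdc <- function(sem) {
  stop_if(any(sem < 0), "sem must be >= 0")
  1.96 * sem * sqrt(2)
}

#' Full agreement statistics for one parameter
#'
#' Assembles one report row: mean difference and SD, limits of agreement,
#' paired-t p, Pearson r with its grade, ICC(2,1) with its p, the
#' Passing-Bablok slope and intercept, SEM and SDC.
#'
#' @inheritParams bland_altman
#' @param sd_basis SD fed into the SEM: `"differences"` (SD of the paired
#'   differences, default) or `"pooled"` (SD of all 2n measurements).
#' @param round_sem Round the SEM to 2 decimals before computing the SDC
#'   (printed-report mode); full precision is the default.
#' @return An object of class `la_agreement` (a list of the statistics).
#' @export
agreement_stats <- function(p, y = NULL, sd_basis = c("differences", "pooled"),
                            round_sem = FALSE) {
  sd_basis <- match.arg(sd_basis)
  p <- as_paired(p, y)
  ba <- bland_altman(p)
  tt <- paired_t(p)
  r <- unname(suppressWarnings(cor(p$x, p$y)))
  icc <- icc_two_way_random(p)
  pb <- passing_bablok(p)
  sd_use <- if (sd_basis == "differences") ba$sd_diff else sd(c(p$x, p$y))
  sem_v <- sem(sd_use, max(0, min(1, icc$icc)))
  if (round_sem) sem_v <- round(sem_v, 2)
  out <- list(parameter = p$parameter, units = p$units, n = p$n,
              mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
              loa_low = ba$loa_low, loa_high = ba$loa_high,
              t_p = tt$p_value, pearson_r = r,
              pearson_grade = pearson_grade(r),
              icc = icc$icc, icc_p = icc$p_value,
              pb_slope = pb$slope, pb_intercept = pb$intercept,
              sem = sem_v, sdc = sdc(sem_v),
              sd_basis = sd_basis)
  class(out) <- "la_agreement"
  out
}

#' @export
print.la_agreement <- function(x, ...) {
  cat(sprintf("%s%s (n = %d)\n", x$parameter,
              if (nzchar(x$units)) paste0(" (", x$units, ")") else "", x$n))
  cat(sprintf("  difference %.3f +/- %.3f, LoA [%.3f, %.3f], t p = %.3g\n",
              x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, x$t_p))
  cat(sprintf("  Pearson r %.3f (%s); ICC %.3f (p = %.3g)\n",
              x$pearson_r, x$pearson_grade, x$icc, x$icc_p))
  cat(sprintf("  Passing-Bablok slope %.3f, intercept %.3f\n",
              x$pb_slope, x$pb_intercept))
  cat(sprintf("  SEM %.2f, SDC %.2f\n", x$sem, x$sdc))
  invisible(x)
}

#' Reliability report table over several parameters
#'
#' One [agreement_stats()] row per parameter; parameters whose statistics
#' fail (for example, zero between-subject variance) are kept in the table
#' with `NA` values and the error message in the `note` column rather than
#' silently dropped.
#'
#' @param pairs A named list of [paired_measurements()] (such as from
#'   [read_paired_csv()]).
#' @param ... Passed to [agreement_stats()].
#' @return A `data.frame` of class `la_agreement_table`.
#' @export
reproducibility_table <- function(pairs, ...) {
  stop_if(length(pairs) < 1, "need at least one parameter")
  rows <- lapply(pairs, function(p) {
    res <- tryCatch(agreement_stats(p, ...), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(parameter = p$parameter, units = p$units, n = p$n,
                 mean_diff = NA_real_, sd_diff = NA_real_,
                 loa_low = NA_real_, loa_high = NA_real_, t_p = NA_real_,
                 pearson_r = NA_real_, pearson_grade = NA_character_,
                 icc = NA_real_, icc_p = NA_real_, pb_slope = NA_real_,
                 pb_intercept = NA_real_, sem = NA_real_, sdc = NA_real_,
                 note = conditionMessage(res))
    } else {
      data.frame(res[c("parameter", "units", "n", "mean_diff", "sd_diff",
                       "loa_low", "loa_high", "t_p", "pearson_r",
                       "pearson_grade", "icc", "icc_p", "pb_slope",
                       "pb_intercept", "sem", "sdc")],
                 note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("la_agreement_table", "data.frame")
  out
}

#' @export
print.la_agreement_table <- function(x, digits = 3, ...) {
  cat("Agreement / reliability report\n")
  df <- as.data.frame(x)
  df$`difference` <- sprintf("%.2f +/- %.2f", df$mean_diff, df$sd_diff)
  show <- df[, c("parameter", "n", "difference", "t_p", "pearson_r",
                 "pearson_grade", "icc", "icc_p", "sem", "sdc", "note")]
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], function(v) signif(v, digits))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write an agreement table to CSV or JSON
#'
#' @param tbl An `la_agreement_table`.
#' @param path Output `.csv` or `.json` path.
#' @return Invisibly, `path`.
#' @export
write_agreement <- function(tbl, path) {
  stopifnot(inherits(tbl, "la_agreement_table"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.csv(as.data.frame(tbl), path, row.names = FALSE)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(tbl), path, auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else stop("use a .csv or .json path", call. = FALSE)
  invisible(path)
}

#' Bland-Altman plot
#'
#' Differences against pair means with the mean difference (solid) and the
#' 95% limits of agreement (dashed).
#'
#' @param x An [paired_measurements()].
#' @param ... Passed to `plot`.
#' @export
plot.la_paired <- function(x, ...) {
  ba <- bland_altman(x)
  mns <- (x$x + x$y) / 2
  d <- x$x - x$y
  plot(mns, d, xlab = sprintf("mean of %s and %s", x$labels[1], x$labels[2]),
       ylab = sprintf("difference (%s - %s)", x$labels[1], x$labels[2]),
       main = sprintf("%s: Bland-Altman", x$parameter), ...)
  abline(h = ba$mean_diff)
  abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(x)
}
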