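make_series_with_corrected <- function(position, corrected) {
  ser <- make_series(position, corrected)
  ser$corrected <- corrected
  ser
}

make_series <- function(position, value) {
  structure(tibble::tibble(position = as.integer(position), value = value,
                           filled = FALSE),
            class = c("residue_series", "tbl_df", "tbl", "data.frame"),
            window = if (length(position) > 0) range(as.integer(position)))
}

# independently coded truncated sliding-mean subtraction
naive_detrend <- function(v, w) {
  h <- (w - 1) / 2
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    lo <- max(1, i - h)
    hi <- min(length(v), i + h)
    acc <- 0
    for (j in lo:hi) acc <- acc + v[j]
    out[i] <- v[i] - acc / (hi - lo + 1)
  }
  out
}

test_that("detrending removes the windowed mean, truncating at edges", {
  const <- make_series(31:60, rep(0.7, 30))
  expect_equal(detrend(const, 5)$corrected, rep(0, 30))

  ramp <- make_series(1:5, 1:5)
  expect_equal(detrend(ramp, 5)$corrected[3], 0)

  set.seed(5)
  v <- runif(52)
  ser <- make_series(31:82, v)
  for (w in c(5, 7, 9, 11)) {
    expect_equal(detrend(ser, w)$corrected, naive_detrend(v, w),
                 tolerance = 1e-12)
  }

  expect_error(detrend(ser, 4), "odd")
  expect_error(detrend(ser, 53), "odd integer|<=")
  expect_error(detrend(make_series(c(31:40, 42), runif(11)), 5), "contiguous")
})

test_that("missing positions are filled with the WT score and flagged", {
  ser <- make_series(c(31:37, 39:45), runif(14))
  filled <- fill_missing(ser, window = c(31, 45))
  expect_equal(nrow(filled), 15)
  expect_equal(filled$value[filled$position == 38], 1.0)
  expect_true(filled$filled[filled$position == 38])
  expect_false(any(filled$filled[filled$position != 38]))

  # nothing missing -> identity on values
  full <- make_series(31:45, runif(15))
  expect_equal(fill_missing(full)$value, full$value)
  expect_false(any(fill_missing(full)$filled))

  # fully absent window -> flat WT series plus a warning
  expect_warning(flat <- fill_missing(make_series(integer(), numeric()),
                                      window = c(31, 40)),
                 "no measured")
  expect_equal(flat$value, rep(1, 10))
  expect_true(all(flat$filled))
})

test_that("score_series extracts per-position Asp values from a score table", {
  sc <- score_table_of(c(31:40, 36L), c(runif(10), 0.2),
                       mut_aa = c(rep("D", 10), "R"), window = c(31, 42))
  ser <- score_series(sc)
  expect_equal(nrow(ser), 10) # the Arg row is excluded
  expect_equal(ser$position, 31:40)
  filled <- fill_missing(ser)
  expect_equal(filled$position, 31:42)
  expect_true(all(filled$filled[filled$position > 40]))
})

test_that("noiseless sinusoids are recovered to 1e-6 across the model class", {
  set.seed(41)
  x <- 45:66
  for (i in 1:50) {
    a <- runif(1, 0.05, 0.5)
    b <- runif(1, 2.2, 7.5)
    cc <- runif(1, 0, 2 * pi)
    fit <- fit_sinusoid(x, a * sin(2 * pi * x / b + cc))
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    dphi <- (fit$c - cc) %% (2 * pi)
    expect_lt(min(dphi, 2 * pi - dphi), 1e-5)
    expect_equal(fit$r, 1, tolerance = 1e-9)
  }
})

test_that("sinusoid fitting is phase-wrap safe", {
  x <- 31:52
  y1 <- 0.2 * sin(2 * pi * x / 3.6 + 1.0)
  y2 <- 0.2 * sin(2 * pi * x / 3.6 + 1.0 + 2 * pi)
  f1 <- fit_sinusoid(x, y1)
  f2 <- fit_sinusoid(x, y2)
  expect_equal(f1$sse, f2$sse, tolerance = 1e-12)
  expect_equal(f1$b, f2$b, tolerance = 1e-9)
})

test_that("profiled fit matches a dense brute-force (a, b, c) grid search", {
  set.seed(13)
  x <- 45:66
  y <- 0.2 * sin(2 * pi * x / 3.6 + 1.0) + rnorm(length(x), 0, 0.05)
  fit <- fit_sinusoid(x, y)
  # independent oracle: dense grid over b and c, amplitude solved per point
  best <- Inf
  sy2 <- sum(y^2)
  for (b in seq(2, 8, by = 0.01)) {
    w <- 2 * pi / b
    for (cc in seq(0, 2 * pi, by = 0.02)) {
      s <- sin(w * x + cc)
      sse <- sy2 - sum(y * s)^2 / sum(s^2)
      if (sse < best) best <- sse
    }
  }
  expect_lte(fit$sse, best + 1e-6)
})

test_that("segment fits beat a single global sinusoid across a phase jump", {
  x <- 31:82
  y <- ifelse(x < 57, 0.25 * sin(2 * pi * x / 3.6 + 0.5),
              0.25 * sin(2 * pi * x / 3.6 + 0.5 + pi))
  ser <- make_series(x, y)
  ser$corrected <- y
  two <- fit_segments(ser, breakpoints = 57)
  expect_equal(length(two$fits), 2)
  expect_lt(sum(purrr::map_dbl(two$fits, "sse")), two$global$sse)

  one <- fit_segments(make_series_with_corrected(x, 0.2 * sin(2 * pi * x / 3.49)),
                      breakpoints = NULL)
  expect_equal(length(one$fits), 1)
  expect_equal(one$fits[[1]]$r, 1, tolerance = 1e-9)
  expect_equal(one$fits[[1]]$b, 3.49, tolerance = 1e-6)

  expect_error(fit_segments(ser, breakpoints = c(34)), "at least 6")
  expect_error(fit_segments(ser, breakpoints = c(20)), "inside")
})

test_that("breakpoint scan finds a phase change and resists overfitting", {
  set.seed(21)
  x <- 31:82
  truth_break <- 57L
  y <- ifelse(x < truth_break, 0.25 * sin(2 * pi * x / 3.6 + 0.3),
              0.25 * sin(2 * pi * x / 3.6 + 0.3 + pi)) +
    rnorm(length(x), 0, 0.02)
  scan <- scan_breakpoints(make_series_with_corrected(x, y), n_breaks = 2)
  expect_gte(length(scan$breakpoints), 1)
  expect_lte(min(abs(scan$breakpoints - truth_break)), 1)

  pure <- 0.2 * sin(2 * pi * x / 3.6 + 1)
  scan0 <- scan_breakpoints(make_series_with_corrected(x, pure), n_breaks = 2)
  expect_length(scan0$breakpoints, 0)
})

test_that("periodicity maps onto secondary-structure labels", {
  expect_equal(assign_structure(3.49)$label, "alpha-helix")
  expect_equal(assign_structure(3.28)$label, "alpha-helix")
  expect_equal(assign_structure(2.0)$label, "strand-like")
  expect_equal(assign_structure(2.8)$label, "irregular/ambiguous")
  expect_equal(assign_structure(6.5)$label, "irregular/ambiguous")
  fit <- fit_sinusoid(31:52, 0.2 * sin(2 * pi * (31:52) / 3.6))
  lab <- assign_structure(fit)
  expect_equal(lab$label, "alpha-helix")
  expect_equal(lab$se, fit$se_b)
})
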