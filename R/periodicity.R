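#' Per-position residue series of binding scores
#'
#' Extracts one score per residue position from a score table (by default the
#' aspartate-substitution `mfi_ratio_mean`), as the series whose periodicity
#' carries the local-structure signal. Positions with several matching
#' substitutions are averaged. The result may have gaps; [fill_missing()]
#' completes it to a contiguous window.
#'
#' @inheritParams call_interface_residues
#' @param mut_aa Substitution(s) to extract (default Asp).
#' @return A tibble of class `residue_series` with columns `position`,
#'   `value`, `filled` (logical; all `FALSE` here).
#' @export
score_series <- function(scores, mut_aa = "D", window = NULL) {
  tbl <- filter(as_tibble(scores), .data$mut_aa %in% .env$mut_aa,
                !is.na(.data$position))
  ser <- tbl |>
    group_by(.data$position) |>
    summarise(value = mean(.data$mfi_ratio_mean), .groups = "drop") |>
    mutate(filled = FALSE) |>
    arrange(.data$position)
  window <- window %||% attr(scores, "sequence_window")
  attr(ser, "window") <- if (!is.null(window)) as.integer(window) else
    range(ser$position)
  class(ser) <- c("residue_series", class(ser))
  ser
}

#' Fill positions with no mutational data
#'
#' Positions inside the window that lack a measured substitution are assigned
#' the WT score (1.0 by default, i.e. assumed mutationally silent) and flagged
#' in `filled`, so later stages can include or exclude them.
#'
#' @param series A `residue_series` (see [score_series()]), possibly with gaps.
#' @param window Integer length-2 first/last position; defaults to the series'
#'   window attribute, else its position range.
#' @param fill_value Value assigned to missing positions (WT score).
#' @return A contiguous `residue_series` covering every position in `window`.
#' @export
fill_missing <- function(series, window = NULL, fill_value = 1) {
  window <- window %||% attr(series, "window") %||%
    (if (nrow(series) > 0) range(series$position) else NULL)
  if (is.null(window)) {
    abort("cannot infer window for an empty series; supply `window`",
          class = "chargescan_validation")
  }
  all_pos <- seq(as.integer(window[1]), as.integer(window[2]))
  if (nrow(series) == 0 || all(!all_pos %in% series$position)) {
    warn("series has no measured positions; returning a flat WT-valued series")
  }
  out <- tibble(position = all_pos) |>
    left_join(as_tibble(series)[, c("position", "value")], by = "position") |>
    mutate(filled = is.na(.data$value),
           value = ifelse(is.na(.data$value), fill_value, .data$value))
  attr(out, "window") <- as.integer(window)
  class(out) <- c("residue_series", class(out))
  out
}

#' Sliding-window detrending of a residue series
#'
#' Subtracts from each position's value the mean over a window of `window`
#' residues centred on it (truncated at the series edges), removing the slow,
#' region-specific component of the mutational-effect profile so that the
#' short-range (helical-face) periodicity is exposed. The default 5-residue
#' window spans ~1.4 helical turns.
#'
#' @param series A contiguous `residue_series` (run [fill_missing()] first if
#'   there are gaps).
#' @param window Odd integer window width, >= 3 and <= series length.
#' @return The series with an added `corrected` column
#'   (`value - sliding mean`).
#' @export
detrend <- function(series, window = 5) {
  n <- nrow(series)
  if (length(window) != 1 || !is.finite(window) || window != round(window) ||
      window %% 2 == 0 || window < 3 || window > n) {
    abort("window must be an odd integer, >= 3 and <= the series length",
          class = "chargescan_validation")
  }
  if (any(diff(series$position) != 1)) {
    abort("series positions must be contiguous; run fill_missing() first",
          class = "chargescan_validation")
  }
  h <- (window - 1) / 2
  v <- series$value
  avg <- vapply(seq_len(n), function(i) {
    mean(v[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  out <- mutate(as_tibble(series), corrected = .data$value - avg)
  attr(out, "window") <- attr(series, "window")
  class(out) <- c("residue_series", class(out))
  out
}

series_xy <- function(series) {
  y <- if ("corrected" %in% names(series)) series$corrected else series$value
  list(x = series$position, y = y)
}

#' Fit a sinusoid to per-residue values
#'
#' Least-squares fit of `y = a * sin(2*pi*x/b + c)` with `x` the absolute
#' residue index. For fixed periodicity `b` the model is linear in
#' `(a*cos(c), a*sin(c))`, so amplitude and phase are solved exactly and only
#' `b` is profiled: a dense deterministic grid over `b_range` followed by 1-D
#' refinement. The fit is therefore deterministic and globally optimal over
#' the profiled range (up to grid resolution). Amplitude is reported >= 0 with
#' phase in `[0, 2*pi)`.
#'
#' @param x A `residue_series` (its `corrected` values are used when present),
#'   or a numeric vector of residue positions.
#' @param y Values at `x` (omit when `x` is a series).
#' @param b_range Periodicity search range in residues/cycle; the default
#'   `[2, 8]` covers strand (~2) through loose-helix periodicities.
#' @param b_step Profile grid step for `b`.
#' @return An object of class `sinusoid_fit`: `segment`, `a`, `b`, `c`, `r`
#'   (correlation of fitted vs observed), `sse`, asymptotic standard errors
#'   `se_a`, `se_b`, `se_c`, `n`, and the per-position `data`. Has `tidy()`,
#'   `glance()` and `print()` methods.
#' @export
fit_sinusoid <- function(x, y = NULL, b_range = c(2, 8), b_step = 0.02) {
  if (is.data.frame(x)) {
    xy <- series_xy(x)
    x <- xy$x
    y <- xy$y
  }
  if (length(x) != length(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("x and y must be equal-length finite vectors",
          class = "chargescan_validation")
  }
  n <- length(x)
  if (n < 6) {
    abort("segment too short to fit a sinusoid (need >= 6 residues)",
          class = "chargescan_validation")
  }
  profile <- function(b) {
    w <- 2 * pi / b
    f <- stats::.lm.fit(cbind(sin(w * x), cos(w * x)), y)
    sum(f$residuals^2)
  }
  grid <- seq(b_range[1], b_range[2], by = b_step)
  sse_grid <- vapply(grid, profile, numeric(1))
  i <- which.min(sse_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(profile, interval = c(lo, hi), tol = 1e-10)
  b <- if (opt$objective <= sse_grid[i]) opt$minimum else grid[i]

  w <- 2 * pi / b
  f <- stats::.lm.fit(cbind(sin(w * x), cos(w * x)), y)
  A <- f$coefficients[1]
  B <- f$coefficients[2]
  a <- sqrt(A^2 + B^2)
  cph <- atan2(B, A) %% (2 * pi)
  fitted <- a * sin(w * x + cph)
  sse <- sum((y - fitted)^2)
  r <- if (stats::sd(fitted) > 0 && stats::sd(y) > 0) cor(y, fitted) else NA_real_

  se <- sinusoid_se(x, y, a, b, cph, sse)
  structure(
    list(segment = c(min(x), max(x)), a = a, b = b, c = cph, r = r, sse = sse,
         se_a = se[1], se_b = se[2], se_c = se[3], n = n,
         data = tibble(position = x, observed = y, fitted = fitted)),
    class = "sinusoid_fit"
  )
}

# asymptotic standard errors from the Jacobian at the optimum
sinusoid_se <- function(x, y, a, b, cph, sse) {
  n <- length(x)
  if (n <= 3) return(rep(NA_real_, 3))
  w <- 2 * pi / b
  cosr <- cos(w * x + cph)
  J <- cbind(sin(w * x + cph),
             a * cosr * (-2 * pi * x / b^2),
             a * cosr)
  sigma2 <- sse / (n - 3)
  V <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, 3))
  sqrt(pmax(diag(V), 0))
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sinusoid fit over residues %d-%d: a = %.4f, b = %.3f +/- %.2g res/cycle, c = %.3f rad; R = %.3f, SSE = %.4g\n",
    x$segment[1], x$segment[2], x$a, x$b, x$se_b, x$c, x$r, x$sse))
  invisible(x)
}

#' @rdname fit_sinusoid
#' @param ... Unused.
#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"),
         estimate = c(x$a, x$b, x$c),
         std.error = c(x$se_a, x$se_b, x$se_c))
}

#' @rdname fit_sinusoid
#' @export
glance.sinusoid_fit <- function(x, ...) {
  tibble(first = x$segment[1], last = x$segment[2], a = x$a, b = x$b, c = x$c,
         se_b = x$se_b, r = x$r, sse = x$sse, n = x$n)
}

#' Fit separate sinusoids to residue segments
#'
#' Splits the detrended series at the given breakpoints and fits each segment
#' independently with [fit_sinusoid()]; the single-segment (no-breakpoint) fit
#' is also computed for comparison, since a global sinusoid is typically a
#' poor model when the waveform changes phase along the chain.
#'
#' @param series A detrended contiguous `residue_series`.
#' @param breakpoints Positions at which a new segment STARTS (e.g.
#'   `c(45, 67)` splits `31..82` into `31-44`, `45-66`, `67-82`). `NULL` or
#'   empty for a single segment.
#' @inheritParams fit_sinusoid
#' @return An object of class `segment_fits`: `fits` (one `sinusoid_fit` per
#'   segment), `global` (the no-breakpoint fit), `breakpoints`. `tidy()` gives
#'   one row per segment with the assigned structure label.
#' @export
fit_segments <- function(series, breakpoints = NULL, b_range = c(2, 8),
                         b_step = 0.02) {
  xy <- series_xy(series)
  pos <- xy$x
  breakpoints <- sort(unique(as.integer(breakpoints)))
  if (length(breakpoints) > 0 &&
      (min(breakpoints) <= min(pos) || max(breakpoints) > max(pos))) {
    abort("breakpoints must lie strictly inside the series",
          class = "chargescan_validation")
  }
  starts <- c(min(pos), breakpoints)
  ends <- c(breakpoints - 1L, max(pos))
  if (any(ends - starts + 1 < 6)) {
    abort("every segment must span at least 6 residues",
          class = "chargescan_validation")
  }
  fits <- purrr::map2(starts, ends, function(s, e) {
    keep <- pos >= s & pos <= e
    fit_sinusoid(pos[keep], xy$y[keep], b_range = b_range, b_step = b_step)
  })
  global <- if (length(breakpoints) > 0) {
    fit_sinusoid(pos, xy$y, b_range = b_range, b_step = b_step)
  } else {
    fits[[1]]
  }
  structure(list(fits = fits, global = global, breakpoints = breakpoints),
            class = "segment_fits")
}

#' @export
print.segment_fits <- function(x, ...) {
  cat("Segment-wise sinusoid fits",
      if (length(x$breakpoints) > 0)
        sprintf("(breakpoints at %s)", paste(x$breakpoints, collapse = ", "))
      else "(single segment)", "\n")
  for (f in x$fits) print(f)
  if (length(x$breakpoints) > 0) {
    cat(sprintf("Global single-segment fit for comparison: R = %.3f, SSE = %.4g\n",
                x$global$r, x$global$sse))
  }
  invisible(x)
}

#' @rdname fit_segments
#' @param x A `segment_fits`.
#' @param ... Unused.
#' @export
tidy.segment_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    mutate(glance(f), label = assign_structure(f)$label)
  })
}

#' @rdname fit_segments
#' @export
glance.segment_fits <- function(x, ...) {
  tibble(n_segments = length(x$fits),
         total_sse = sum(purrr::map_dbl(x$fits, "sse")),
         global_sse = x$global$sse,
         breakpoints = paste(x$breakpoints, collapse = ","))
}

#' Automatic breakpoint search for segment-wise sinusoid fits
#'
#' Exhaustively searches placements of up to `n_breaks` breakpoints
#' (each segment at least `min_len` residues) minimizing an AICc-penalized
#' residual sum of squares (3 sinusoid parameters per segment, plus the noise
#' variance), so extra segments must earn their keep. Ties are broken toward
#' fewer, then later, breakpoints. Deterministic.
#'
#' @inheritParams fit_segments
#' @param n_breaks Maximum number of breakpoints (0, 1 or 2).
#' @param min_len Minimum segment length in residues.
#' @return A list with `breakpoints` (chosen positions, possibly empty),
#'   `fits` (a `segment_fits` refit at fine resolution), and `search`
#'   (tibble of all candidate models with their SSE and AICc).
#' @export
scan_breakpoints <- function(series, n_breaks = 2, min_len = 8,
                             b_range = c(2, 8), b_step = 0.02) {
  if (n_breaks < 0 || n_breaks > 2) {
    abort("n_breaks must be 0, 1 or 2", class = "chargescan_validation")
  }
  if (min_len < 6) {
    abort("min_len must be >= 6 (sinusoid fits need 6 residues)",
          class = "chargescan_validation")
  }
  xy <- series_xy(series)
  pos <- xy$x
  n <- length(pos)
  if (n < (n_breaks + 1) * min_len) {
    abort(sprintf("series too short for %d breakpoint(s) with min_len %d",
                  n_breaks, min_len), class = "chargescan_validation")
  }
  # coarse profile SSE for every admissible contiguous segment [i, j] (indices)
  seg_sse <- function(i, j) {
    f <- fit_sinusoid(pos[i:j], xy$y[i:j], b_range = b_range, b_step = 0.05)
    f$sse
  }
  memo <- new.env(parent = emptyenv())
  sse_of <- function(i, j) {
    key <- paste(i, j)
    if (is.null(memo[[key]])) memo[[key]] <- seg_sse(i, j)
    memo[[key]]
  }
  aicc <- function(sse, m) {
    p <- 3 * m + 1
    if (n - p - 1 <= 0) return(Inf)
    n * log(sse / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  }
  candidates <- list(list(breaks = integer(0)))
  if (n_breaks >= 1) {
    for (s in seq(min_len + 1, n - min_len + 1)) {
      candidates <- c(candidates, list(list(breaks = s)))
    }
  }
  if (n_breaks >= 2) {
    for (s1 in seq(min_len + 1, n - 2 * min_len + 1)) {
      for (s2 in seq(s1 + min_len, n - min_len + 1)) {
        candidates <- c(candidates, list(list(breaks = c(s1, s2))))
      }
    }
  }
  rows <- purrr::map_dfr(candidates, function(cand) {
    br <- cand$breaks
    starts <- c(1L, br)
    ends <- c(br - 1L, n)
    sse <- sum(purrr::map2_dbl(starts, ends, sse_of))
    tibble(breakpoints = paste(pos[br], collapse = ","),
           n_segments = length(starts), sse = sse,
           aicc = aicc(sse, length(starts)))
  })
  # selection: min AICc; ties -> fewer segments, then later breakpoints
  idx_breaks <- purrr::map(candidates, "breaks")
  ord <- order(rows$aicc,
               rows$n_segments,
               -purrr::map_dbl(idx_breaks, function(b)
                 if (length(b) == 0) Inf else sum(b)))
  best <- idx_breaks[[ord[1]]]
  fits <- fit_segments(series,
                       breakpoints = if (length(best) > 0) pos[best] else NULL,
                       b_range = b_range, b_step = b_step)
  list(breakpoints = if (length(best) > 0) pos[best] else integer(0),
       fits = fits, search = arrange(rows, .data$aicc))
}

#' Assign a secondary-structure label from fitted periodicity
#'
#' Interprets the residues-per-cycle periodicity of a mutational-effect
#' sinusoid: ~3.6 residues/turn is the canonical alpha-helical repeat
#' (labelled for `3.2 <= b <= 4.1`), ~2 residues/cycle is the beta-strand
#' register (`1.8 <= b <= 2.2`); anything else is irregular/ambiguous.
#'
#' @param fit A `sinusoid_fit`, or a numeric periodicity in residues/cycle.
#' @param se Optional standard error of the periodicity (taken from the fit
#'   when available).
#' @return A tibble with `periodicity`, `se`, `label` and `rationale`.
#' @export
assign_structure <- function(fit, se = NA_real_) {
  if (inherits(fit, "sinusoid_fit")) {
    b <- fit$b
    se <- fit$se_b
  } else {
    b <- as.numeric(fit)
  }
  label <- dplyr::case_when(
    b >= 3.2 & b <= 4.1 ~ "alpha-helix",
    b >= 1.8 & b <= 2.2 ~ "strand-like",
    .default = "irregular/ambiguous"
  )
  rationale <- dplyr::case_when(
    label == "alpha-helix" ~
      sprintf("periodicity %.2f residues/cycle is consistent with the canonical ~3.6-residue helical turn", b),
    label == "strand-like" ~
      sprintf("periodicity %.2f residues/cycle matches the ~2-residue strand register", b),
    .default =
      sprintf("periodicity %.2f residues/cycle matches neither the helical (~3.6) nor strand (~2) repeat", b)
  )
  tibble(periodicity = b, se = se, label = label, rationale = rationale)
}
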