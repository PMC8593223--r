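#' Exact 1-D two-means clustering
#'
#' Returns the globally optimal two-cluster partition of a 1-D sample under
#' the k-means objective (minimum within-cluster sum of squared deviations).
#' In one dimension the optimal clusters are contiguous in sorted order, so
#' the optimum is found exactly by scanning the n-1 sorted split points with
#' prefix sums -- no Lloyd iteration, no seed dependence.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return A list with `centers` (ascending cluster means), `labels`
#'   (1 = lower-mean cluster, 2 = higher-mean cluster, in input order),
#'   `within_sse` (total within-cluster sum of squares) and `sizes`.
#' @export
two_means_1d <- function(values) {
  if (any(!is.finite(values))) {
    abort("values must be finite", class = "chargescan_validation")
  }
  n <- length(values)
  if (n < 2 || length(unique(values)) < 2) {
    abort("degenerate clustering: need at least 2 distinct values",
          class = "chargescan_validation")
  }
  o <- order(values)
  x <- values[o]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  sse_left <- cs2[k] - cs[k]^2 / k
  sse_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  total <- sse_left + sse_right
  best <- which.min(total)
  labels_sorted <- rep(c(1L, 2L), times = c(best, n - best))
  labels <- integer(n)
  labels[o] <- labels_sorted
  centers <- c(cs[best] / best, (cs[n] - cs[best]) / (n - best))
  list(centers = centers, labels = labels,
       within_sse = total[best], sizes = c(best, n - best))
}

#' Binding-defective threshold from the WT-like class
#'
#' The cutoff below which a mutant is categorized as binding defective:
#' the mean of the WT-like (higher-scoring) class minus one standard deviation
#' of that class.
#'
#' @param x Either an [classify_interface()] result, or the WT-like class mean
#'   (with `class1_sd` supplied).
#' @param class1_sd Standard deviation of the WT-like class (numeric method).
#' @param ... Unused.
#' @return The threshold (unitless score).
#' @export
#' @examples
#' defective_threshold(0.89, 0.07) # 0.82
defective_threshold <- function(x, ...) UseMethod("defective_threshold")

#' @rdname defective_threshold
#' @export
defective_threshold.interface_classification <- function(x, ...) {
  x$class1_mean - x$class1_sd
}

#' @rdname defective_threshold
#' @export
defective_threshold.numeric <- function(x, class1_sd, ...) {
  if (any(!is.finite(x)) || any(!is.finite(class1_sd)) || any(class1_sd < 0)) {
    abort("class mean and sd must be finite, sd >= 0",
          class = "chargescan_validation")
  }
  x - class1_sd
}

#' Call binding-interface residues from a score table
#'
#' A position is called as interface if ANY charged substitution considered at
#' it (aspartate or arginine by default) scores strictly below the threshold
#' ("lower than", so ties are not called). Positions inside the scanned window
#' with no considered substitution at all are reported as uncovered, not as
#' negative.
#'
#' @param scores A `score_table` (see [score_panel()]).
#' @param threshold Unitless score cutoff, e.g. from [defective_threshold()].
#' @param call_aa Substitutions whose scores can trigger a call.
#' @param window Scanned residue window; defaults to the score table's
#'   `sequence_window` attribute.
#' @return A list with `interface` (sorted called positions) and `uncovered`
#'   (positions with no considered substitution data).
#' @export
call_interface_residues <- function(scores, threshold,
                                    call_aa = c("D", "R"), window = NULL) {
  tbl <- filter(as_tibble(scores), .data$mut_aa != "WT")
  if (nrow(tbl) == 0) {
    abort("empty score table", class = "chargescan_validation")
  }
  window <- window %||% attr(scores, "sequence_window") %||%
    range(tbl$position, na.rm = TRUE)
  considered <- filter(tbl, .data$mut_aa %in% call_aa)
  called <- considered$position[considered$mfi_ratio_mean < threshold]
  covered <- unique(considered$position)
  list(interface = sort(unique(called)),
       uncovered = setdiff(seq(window[1], window[2]), covered))
}

#' Two-class partition of mutational effects and interface calls
#'
#' Clusters the aspartate-substitution binding scores into two classes by
#' exact 1-D two-means ([two_means_1d()]): class 1 is the WT-like class
#' (larger mean), class 2 the binding-defective class. The threshold
#' `class1_mean - class1_sd` is then applied to all considered charged
#' substitutions (aspartate and arginine) to call interface residues, so
#' positions lacking an Asp mutant are callable from Arg data alone.
#'
#' @inheritParams call_interface_residues
#' @param fit_aa Substitution(s) whose scores are clustered (default Asp).
#' @param call_aa Substitution(s) the threshold is applied to.
#' @return An object of class `interface_classification`: class means/sds,
#'   `threshold`, per-mutant `labels` tibble (class assignment by nearest
#'   center and call flag), `interface_calls`, `uncovered`, and the clustering
#'   `within_sse`. Has `tidy()`, `glance()`, `print()` and `autoplot()`
#'   methods.
#' @export
classify_interface <- function(scores, fit_aa = "D", call_aa = c("D", "R"),
                               window = NULL) {
  tbl <- filter(as_tibble(scores), .data$mut_aa != "WT")
  if (nrow(tbl) == 0) {
    abort("empty score table", class = "chargescan_validation")
  }
  fit_tbl <- filter(tbl, .data$mut_aa %in% fit_aa)
  if (nrow(fit_tbl) < 2) {
    abort(sprintf("need at least 2 %s-substitution scores to cluster",
                  paste(fit_aa, collapse = "/")),
          class = "chargescan_validation")
  }
  km <- two_means_1d(fit_tbl$mfi_ratio_mean)
  # class 1 = WT-like = larger mean
  hi <- which.max(km$centers)
  lo <- 3L - hi
  members1 <- fit_tbl$mfi_ratio_mean[km$labels == hi]
  members2 <- fit_tbl$mfi_ratio_mean[km$labels == lo]
  class1_mean <- mean(members1)
  class1_sd <- if (length(members1) > 1) sd(members1) else 0
  class2_mean <- mean(members2)
  class2_sd <- if (length(members2) > 1) sd(members2) else 0
  threshold <- class1_mean - class1_sd

  lab_tbl <- filter(tbl, .data$mut_aa %in% union(fit_aa, call_aa)) |>
    mutate(
      class = ifelse(abs(.data$mfi_ratio_mean - class1_mean) <=
                       abs(.data$mfi_ratio_mean - class2_mean), 1L, 2L),
      called = .data$mut_aa %in% call_aa & .data$mfi_ratio_mean < threshold
    ) |>
    select("position", "wt_aa", "mut_aa", score = "mfi_ratio_mean",
           "class", "called")

  calls <- call_interface_residues(scores, threshold, call_aa = call_aa,
                                   window = window)
  structure(
    list(class1_mean = class1_mean, class1_sd = class1_sd,
         class2_mean = class2_mean, class2_sd = class2_sd,
         threshold = threshold, within_sse = km$within_sse,
         n_fit = nrow(fit_tbl), fit_aa = fit_aa, call_aa = call_aa,
         labels = lab_tbl,
         interface_calls = calls$interface, uncovered = calls$uncovered),
    class = "interface_classification"
  )
}

#' @export
print.interface_classification <- function(x, ...) {
  cat("Two-class partition of", x$n_fit,
      paste0(paste(x$fit_aa, collapse = "/"), "-substitution"), "scores\n")
  cat(sprintf("  class 1 (WT-like):            mean %.3f, sd %.3f\n",
              x$class1_mean, x$class1_sd))
  cat(sprintf("  class 2 (binding-defective):  mean %.3f, sd %.3f\n",
              x$class2_mean, x$class2_sd))
  cat(sprintf("  threshold (mean1 - sd1):      %.3f\n", x$threshold))
  cat(sprintf("  interface calls: %d position(s)\n", length(x$interface_calls)))
  if (length(x$interface_calls) > 0) {
    cat("   ", paste(x$interface_calls, collapse = ", "), "\n")
  }
  if (length(x$uncovered) > 0) {
    cat(sprintf("  uncovered positions: %s\n", paste(x$uncovered, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname classify_interface
#' @param x An `interface_classification`.
#' @param ... Unused.
#' @export
tidy.interface_classification <- function(x, ...) {
  mutate(x$labels, interface = .data$position %in% x$interface_calls)
}

#' @rdname classify_interface
#' @export
glance.interface_classification <- function(x, ...) {
  tibble(class1_mean = x$class1_mean, class1_sd = x$class1_sd,
         class2_mean = x$class2_mean, class2_sd = x$class2_sd,
         threshold = x$threshold, within_sse = x$within_sse,
         n_fit = x$n_fit, n_calls = length(x$interface_calls),
         n_uncovered = length(x$uncovered))
}
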