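#' Mean per-cell binding:expression ratio
#'
#' Given per-cell intensities from the gated population, returns the arithmetic
#' mean over cells of binding/expression. This is the "mean of per-cell ratios"
#' convention (not the ratio of channel means); with summary-only input the
#' scan table's `ratio_mfi` column is used instead.
#'
#' @param cells A data frame (or 2-column matrix) with columns `expression`
#'   and `binding`; one row per cell.
#' @return The mean per-cell ratio (arbitrary units).
#' @export
mean_cell_ratio <- function(cells) {
  cells <- as.data.frame(cells)
  if (is.null(colnames(cells)) || !all(c("expression", "binding") %in% names(cells))) {
    names(cells)[1:2] <- c("expression", "binding")
  }
  if (nrow(cells) == 0) {
    abort("no cells supplied", class = "chargescan_validation")
  }
  if (any(!is.finite(cells$expression)) || any(cells$expression <= 0)) {
    abort("all per-cell expression intensities must be > 0",
          class = "chargescan_validation")
  }
  mean(cells$binding / cells$expression)
}

#' Normalized expression score (MFIexp)
#'
#' Mutant expression MFI divided by the WT expression MFI; 1 = WT-like surface
#' expression.
#'
#' @param mut_expression_mfi,wt_expression_mfi Expression-channel MFIs (> 0).
#' @return Unitless ratio (vectorized over the mutant argument).
#' @export
compute_mfi_exp <- function(mut_expression_mfi, wt_expression_mfi) {
  if (any(!is.finite(wt_expression_mfi)) || any(wt_expression_mfi <= 0)) {
    abort("WT expression MFI must be > 0", class = "chargescan_validation")
  }
  if (any(!is.finite(mut_expression_mfi)) || any(mut_expression_mfi <= 0)) {
    abort("mutant expression MFI must be > 0", class = "chargescan_validation")
  }
  mut_expression_mfi / wt_expression_mfi
}

#' Normalized binding-activity score (MFIratio)
#'
#' Mutant mean binding:expression ratio MFI divided by the WT value, per
#' replicate. WT scores 1 by construction; 0 means no detectable binding
#' (a valid score, not an error).
#'
#' @param mut_ratio_mfi Mutant mean binding:expression ratio MFI (>= 0).
#' @param wt_ratio_mfi WT mean binding:expression ratio MFI (> 0).
#' @return Unitless ratio (vectorized over the mutant argument).
#' @export
compute_mfi_ratio <- function(mut_ratio_mfi, wt_ratio_mfi) {
  if (any(!is.finite(wt_ratio_mfi)) || any(wt_ratio_mfi <= 0)) {
    abort("WT ratio MFI must be > 0", class = "chargescan_validation")
  }
  if (any(!is.finite(mut_ratio_mfi)) || any(mut_ratio_mfi < 0)) {
    abort("mutant ratio MFI must be >= 0", class = "chargescan_validation")
  }
  mut_ratio_mfi / wt_ratio_mfi
}

#' Score a scan panel
#'
#' Computes, per (position, substitution): the normalized binding-activity
#' score `mfi_ratio` for each replicate against that replicate's own WT
#' reference, then its mean and standard deviation (n-1 denominator) across
#' replicates; and the normalized expression score `mfi_exp` from
#' replicate-mean expression MFIs. Per-replicate normalization makes the
#' scores invariant to channel rescaling within a replicate, which is what
#' permits comparison across experiments.
#'
#' If the panel lacks a `ratio_mfi` column, the record-level ratio falls back
#' to `binding_mfi / expression_mfi`.
#'
#' @param panel A [scan_panel()].
#' @return A tibble of class `score_table` with columns `position`, `wt_aa`,
#'   `mut_aa`, `mfi_exp`, `mfi_ratio_mean`, `mfi_ratio_sd`, `n_replicates`,
#'   including one WT row (both scores exactly 1). Carries the panel's
#'   `sequence_window` attribute.
#' @export
score_panel <- function(panel) {
  validate_scan_panel(panel)
  rec <- as_tibble(panel)
  if (!"ratio_mfi" %in% names(rec) || all(is.na(rec$ratio_mfi))) {
    rec$ratio_mfi <- rec$binding_mfi / rec$expression_mfi
  }
  wt <- rec |>
    filter(.data$mut_aa == "WT") |>
    select(replicate = "replicate", wt_expression = "expression_mfi",
           wt_ratio = "ratio_mfi")
  if (any(wt$wt_ratio <= 0)) {
    abort("WT ratio MFI must be > 0 in every replicate",
          class = "chargescan_validation")
  }
  wt_mean_expression <- mean(wt$wt_expression)

  scored <- rec |>
    filter(.data$mut_aa != "WT") |>
    left_join(wt, by = "replicate") |>
    mutate(norm_ratio = compute_mfi_ratio(.data$ratio_mfi, .data$wt_ratio)) |>
    group_by(.data$position, .data$wt_aa, .data$mut_aa) |>
    summarise(
      mfi_exp = compute_mfi_exp(mean(.data$expression_mfi), wt_mean_expression),
      mfi_ratio_mean = mean(.data$norm_ratio),
      mfi_ratio_sd = if (dplyr::n() > 1) sd(.data$norm_ratio) else NA_real_,
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(.data$position, .data$mut_aa)

  wt_row <- tibble(
    position = NA_integer_, wt_aa = "WT", mut_aa = "WT",
    mfi_exp = 1, mfi_ratio_mean = 1,
    mfi_ratio_sd = if (nrow(wt) > 1) 0 else NA_real_,
    n_replicates = nrow(wt)
  )
  new_tibble(bind_rows(wt_row, scored), class = "score_table",
             sequence_window = attr(panel, "sequence_window"))
}

#' @rdname write_scan_table
#' @param scores A `score_table`.
#' @export
write_score_table <- function(scores, path) {
  readr::write_csv(format_full_precision(as_tibble(scores)), path, progress = FALSE)
  invisible(scores)
}

#' Read a score table written by [write_score_table()]
#'
#' @inheritParams read_scan_table
#' @return A tibble of class `score_table`.
#' @export
read_score_table <- function(path, sequence_window = NULL) {
  df <- convert_columns(read_delim_auto(path),
                        double_cols = c("mfi_exp", "mfi_ratio_mean",
                                        "mfi_ratio_sd"),
                        int_cols = c("position", "n_replicates"))
  needed <- c("position", "wt_aa", "mut_aa", "mfi_exp", "mfi_ratio_mean")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("score table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "chargescan_validation")
  }
  df$position <- as.integer(df$position)
  if ("n_replicates" %in% names(df)) df$n_replicates <- as.integer(df$n_replicates)
  if (is.null(sequence_window)) {
    sequence_window <- range(df$position, na.rm = TRUE)
  }
  new_tibble(df, class = "score_table",
             sequence_window = as.integer(sequence_window))
}
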