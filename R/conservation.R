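#' Correlate mutational tolerance with evolutionary conservation
#'
#' Inner-joins per-position binding scores (aspartate substitutions by
#' default) with a per-position conservation table and reports Pearson and
#' Spearman correlations over the complete pairs. Positions lacking either
#' value are excluded and counted; WT-filled positions never enter because
#' only measured substitutions appear in a score table.
#'
#' @inheritParams call_interface_residues
#' @param cons A [conservation_table()].
#' @param mut_aa Substitution(s) whose scores are correlated (default Asp).
#' @return An object of class `conservation_report` with `pearson_r`,
#'   `spearman_rho`, `n_positions`, `n_dropped` and the paired tibble
#'   `pairs` (`position`, `score`, `conservation`). Has `glance()`,
#'   `print()` and `autoplot()` methods.
#' @export
correlate_conservation <- function(scores, cons, mut_aa = "D") {
  ser <- filter(as_tibble(scores), .data$mut_aa %in% .env$mut_aa,
                !is.na(.data$position)) |>
    group_by(.data$position) |>
    summarise(score = mean(.data$mfi_ratio_mean), .groups = "drop")
  cons_tbl <- select(as_tibble(cons), "position", conservation = "score")
  pairs <- inner_join(ser, cons_tbl, by = "position") |>
    filter(is.finite(.data$score), is.finite(.data$conservation)) |>
    arrange(.data$position)
  n_dropped <- nrow(ser) + nrow(cons_tbl) - 2 * nrow(pairs)
  if (nrow(pairs) < 3) {
    abort("need at least 3 overlapping positions with both score and conservation",
          class = "chargescan_validation")
  }
  structure(
    list(pearson_r = cor(pairs$score, pairs$conservation),
         spearman_rho = cor(pairs$score, pairs$conservation, method = "spearman"),
         n_positions = nrow(pairs), n_dropped = n_dropped, pairs = pairs),
    class = "conservation_report"
  )
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("Score-vs-conservation over %d positions: Pearson r = %.3f, Spearman rho = %.3f (%d unmatched rows dropped)\n",
              x$n_positions, x$pearson_r, x$spearman_rho, x$n_dropped))
  invisible(x)
}

#' @rdname correlate_conservation
#' @param x A `conservation_report`.
#' @param ... Unused.
#' @export
glance.conservation_report <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, spearman_rho = x$spearman_rho,
         n_positions = x$n_positions, n_dropped = x$n_dropped)
}
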