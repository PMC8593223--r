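#' Plot methods
#'
#' `autoplot()` methods for the main result types: per-position score
#' profiles, the two-class partition, segment-wise sinusoid fits over the
#' detrended series, one-site binding fits (log-concentration axis), and the
#' score-vs-conservation scatter.
#'
#' @param object The object to plot.
#' @param threshold Optional horizontal cutoff line for score profiles.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @name chargescan-plots
NULL

#' @rdname chargescan-plots
#' @export
autoplot.score_table <- function(object, threshold = NULL, ...) {
  tbl <- filter(as_tibble(object), .data$mut_aa != "WT")
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$position,
                                         y = .data$mfi_ratio_mean,
                                         colour = .data$mut_aa)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mfi_ratio_mean - .data$mfi_ratio_sd,
      ymax = .data$mfi_ratio_mean + .data$mfi_ratio_sd), width = 0.3,
      na.rm = TRUE) +
    ggplot2::labs(x = "residue position", y = "normalized binding score",
                  colour = "substitution") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' @rdname chargescan-plots
#' @export
autoplot.interface_classification <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$position, y = .data$score,
                                    colour = factor(.data$class),
                                    shape = .data$called)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "residue position", y = "normalized binding score",
                  colour = "class", shape = "called") +
    ggplot2::theme_minimal()
}

#' @rdname chargescan-plots
#' @export
autoplot.segment_fits <- function(object, ...) {
  obs <- purrr::map_dfr(seq_along(object$fits), function(i) {
    mutate(object$fits[[i]]$data, segment = paste0("segment ", i))
  })
  dense <- purrr::map_dfr(seq_along(object$fits), function(i) {
    f <- object$fits[[i]]
    x <- seq(f$segment[1], f$segment[2], by = 0.1)
    tibble(position = x,
           fitted = f$a * sin(2 * pi * x / f$b + f$c),
           segment = paste0("segment ", i))
  })
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$position, colour = .data$segment)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(data = dense, ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "residue position", y = "detrended binding score") +
    ggplot2::theme_minimal()
}

#' @rdname chargescan-plots
#' @export
autoplot.binding_fit <- function(object, ...) {
  dense <- tibble(conc = exp(seq(log(min(object$data$conc)),
                                 log(max(object$data$conc)), length.out = 200)))
  dense$fitted <- predict(object, dense)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$binding_mfi)) +
    ggplot2::geom_line(data = dense, ggplot2::aes(y = .data$fitted)) +
    ggplot2::geom_vline(xintercept = object$kd, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand dimer concentration (nM)", y = "binding MFI",
                  title = sprintf("Kd = %.3g nM", object$kd)) +
    ggplot2::theme_minimal()
}

#' @rdname chargescan-plots
#' @export
autoplot.conservation_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$conservation,
                                             y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "evolutionary conservation",
                  y = "normalized binding score",
                  title = sprintf("Pearson r = %.2f, Spearman rho = %.2f",
                                  object$pearson_r, object$spearman_rho)) +
    ggplot2::theme_minimal()
}
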