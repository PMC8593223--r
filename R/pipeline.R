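#' Configuration for an end-to-end pipeline run
#'
#' Validates and freezes everything a run depends on, so [run_pipeline()] is a
#' pure function of its config (plus the seed it contains): identical configs
#' give identical reports.
#'
#' @param scan A [scan_panel()] or path to a scan table file.
#' @param conservation Optional [conservation_table()] or path.
#' @param titrations Optional named list of [titration_curve()]s or paths
#'   (names = variant ids).
#' @param calibration_pairs Optional data frame (`mfi_ratio`, `kd`) of
#'   reference variants for [calibrate_kd()]. If omitted and titrations carry
#'   variant ids matching `<wt_aa><position><mut_aa>` mutants (or `"WT"`) in
#'   the score table, pairs are assembled automatically.
#' @param window Odd detrending window width (residues).
#' @param breakpoints Integer positions starting new segments, or `"auto"` for
#'   [scan_breakpoints()], or `NULL` for a single segment.
#' @param threshold `"kmeans"` to derive the binding-defective cutoff from the
#'   two-class partition, or an explicit numeric value in (0, 1.5).
#' @param seed Integer seed covering any stochastic stage.
#' @param out_dir Optional directory; when given, every stage output is
#'   written there as plain CSV/JSON.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(scan, conservation = NULL, titrations = NULL,
                       calibration_pairs = NULL, window = 5,
                       breakpoints = c(45, 67), threshold = "kmeans",
                       seed = 1, out_dir = NULL) {
  bad <- function(field, msg) {
    abort(sprintf("invalid run config: `%s` %s", field, msg),
          class = "chargescan_validation")
  }
  if (length(window) != 1 || !is.finite(window) || window != round(window) ||
      window %% 2 == 0) {
    bad("window", "must be a single odd integer")
  }
  if (is.character(threshold)) {
    if (!identical(threshold, "kmeans")) bad("threshold", 'must be "kmeans" or numeric')
  } else if (!is.numeric(threshold) || length(threshold) != 1 ||
             threshold <= 0 || threshold >= 1.5) {
    bad("threshold", "must be in (0, 1.5)")
  }
  check_path <- function(x, field) {
    if (is.character(x) && !file.exists(x)) bad(field, sprintf('file not found: "%s"', x))
  }
  check_path(scan, "scan")
  check_path(conservation, "conservation")
  for (t in titrations) check_path(t, "titrations")
  if (!is.null(breakpoints) && !identical(breakpoints, "auto") &&
      !is.numeric(breakpoints)) {
    bad("breakpoints", 'must be numeric positions, "auto", or NULL')
  }
  structure(list(scan = scan, conservation = conservation,
                 titrations = titrations, calibration_pairs = calibration_pairs,
                 window = as.integer(window), breakpoints = breakpoints,
                 threshold = threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full scanning-mutagenesis analysis pipeline
#'
#' Orchestrates score -> classify -> periodicity -> titrate/calibrate ->
#' conservation on one configuration, collecting every stage output and all
#' warnings (uncovered positions, poorly constrained Kd) into a single
#' machine-readable report. Any stage failure aborts with the stage name.
#' The report is deterministic given the config; the timestamp is the only
#' run-specific field.
#'
#' @param config A [run_config()].
#' @return A list of class `run_report`: `config`, `config_hash`, `scores`,
#'   `classification`, `threshold`, `interface_calls`, `uncovered`, `series`,
#'   `segments`, `titration_fits`, `calibration`, `conservation`, `warnings`,
#'   `timestamp`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("config must be created with run_config()",
          class = "chargescan_validation")
  }
  warnings <- character()
  note <- function(msg) warnings <<- c(warnings, msg)
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
              class = "chargescan_stage_error", parent = e)
      }),
      warning = function(w) {
        note(sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }

  panel <- stage("input", {
    if (is.character(config$scan)) read_scan_table(config$scan) else config$scan
  })
  scores <- stage("score", score_panel(panel))

  classification <- stage("classify", classify_interface(scores))
  threshold <- if (is.numeric(config$threshold)) config$threshold else
    classification$threshold
  calls <- stage("classify", call_interface_residues(scores, threshold))
  if (length(calls$uncovered) > 0) {
    note(sprintf("[classify] %d position(s) uncovered: %s",
                 length(calls$uncovered), paste(calls$uncovered, collapse = ", ")))
  }

  series <- stage("periodicity", {
    score_series(scores) |> fill_missing() |> detrend(window = config$window)
  })
  segments <- stage("periodicity", {
    if (identical(config$breakpoints, "auto")) {
      scan_breakpoints(series)$fits
    } else {
      fit_segments(series, breakpoints = config$breakpoints)
    }
  })

  titration_fits <- NULL
  calibration <- NULL
  if (!is.null(config$titrations)) {
    titration_fits <- stage("titrate", {
      purrr::imap(config$titrations, function(t, id) {
        curve <- if (is.character(t)) read_titration(t, variant_id = id) else t
        fit_one_site(curve)
      })
    })
  }
  pairs <- config$calibration_pairs
  if (is.null(pairs) && !is.null(titration_fits)) {
    pairs <- stage("calibrate", match_calibration_pairs(scores, titration_fits))
  }
  if (!is.null(pairs) && nrow(pairs) >= 3) {
    calibration <- stage("calibrate", calibrate_kd(pairs))
  } else if (!is.null(titration_fits) && is.null(config$calibration_pairs)) {
    note("[calibrate] fewer than 3 matched (score, Kd) pairs; calibration skipped")
  }

  conservation <- NULL
  if (!is.null(config$conservation)) {
    conservation <- stage("conserve", {
      cons <- if (is.character(config$conservation)) {
        read_conservation(config$conservation)
      } else config$conservation
      correlate_conservation(scores, cons)
    })
  }

  hash_cfg <- config
  hash_cfg$out_dir <- NULL
  report <- structure(
    list(config = config,
         config_hash = rlang::hash(hash_cfg),
         scores = scores, classification = classification,
         threshold = threshold,
         interface_calls = calls$interface, uncovered = calls$uncovered,
         series = series, segments = segments,
         titration_fits = titration_fits, calibration = calibration,
         conservation = conservation,
         warnings = warnings, timestamp = Sys.time()),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

# pair titration-fit Kds with score-table mfi_ratio by variant id
match_calibration_pairs <- function(scores, titration_fits) {
  tbl <- as_tibble(scores)
  ids <- paste0(tbl$wt_aa, tbl$position, tbl$mut_aa)
  ids[tbl$mut_aa == "WT"] <- "WT"
  rows <- purrr::compact(purrr::map(titration_fits, function(f) {
    i <- match(f$variant_id, ids)
    if (is.na(i)) return(NULL)
    tibble(mfi_ratio = tbl$mfi_ratio_mean[i], kd = f$kd)
  }))
  if (length(rows) == 0) return(NULL)
  bind_rows(rows)
}

#' Write a run report to plain-text files
#'
#' Emits auditable CSV/JSON intermediates for every stage present in the
#' report: `scores.csv`, `classification.json`, `corrected_series.csv`,
#' `segments.csv`, `titration_fits.csv`, `calibration.json`,
#' `conservation.json` and a `report.json` summary.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_score_table(report$scores, p("scores.csv"))
  jsonlite::write_json(
    c(as.list(glance(report$classification)),
      list(threshold_used = report$threshold,
           interface_calls = report$interface_calls,
           uncovered = report$uncovered)),
    p("classification.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(as_tibble(report$series), p("corrected_series.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(report$segments), p("segments.csv"), progress = FALSE)
  if (!is.null(report$titration_fits)) {
    readr::write_csv(purrr::map_dfr(report$titration_fits, glance),
                     p("titration_fits.csv"), progress = FALSE)
  }
  if (!is.null(report$calibration)) {
    jsonlite::write_json(as.list(glance(report$calibration)),
                         p("calibration.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$conservation)) {
    jsonlite::write_json(as.list(glance(report$conservation)),
                         p("conservation.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(config_hash = report$config_hash,
         threshold = report$threshold,
         n_interface_calls = length(report$interface_calls),
         segments = tidy(report$segments),
         warnings = report$warnings),
    p("report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("chargescan pipeline run", x$config_hash, "\n")
  cat(sprintf("  scored mutants: %d (threshold %.3f, %d interface calls)\n",
              sum(as_tibble(x$scores)$mut_aa != "WT"), x$threshold,
              length(x$interface_calls)))
  print(x$segments)
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$conservation)) print(x$conservation)
  if (length(x$warnings) > 0) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}
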