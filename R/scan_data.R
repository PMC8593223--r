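#' Construct a validated scan panel
#'
#' A scan panel is the tidy measurement table of a charged-residue scanning
#' mutagenesis experiment read out by yeast surface display: one row per
#' (mutant, replicate), holding the expression-channel and binding-channel mean
#' fluorescence intensities (MFI), plus one wild-type (WT) reference row per
#' replicate (`mut_aa == "WT"`, `position` may be `NA`). All downstream scoring
#' is normalized per replicate against that replicate's WT row.
#'
#' @param records A data frame with columns `position` (1-based residue index
#'   along the full protein sequence), `wt_aa`, `mut_aa` (one-letter codes;
#'   `"WT"` marks the reference construct), `replicate` (integer label),
#'   `expression_mfi` (> 0, arbitrary units), `binding_mfi` (>= 0), and
#'   optionally `ratio_mfi` (mean per-cell binding:expression ratio, >= 0).
#' @param sequence_window Integer length-2 vector, first and last residue
#'   position covered by the scan (e.g. `c(31, 82)`). Defaults to the range of
#'   mutant positions present.
#' @param ligand_conc Probe (ligand dimer) concentration in nM used for the
#'   binding stain. Single value.
#'
#' @return A tibble of class `scan_panel` with attributes `sequence_window`
#'   and `ligand_conc`.
#' @export
#' @examples
#' pan <- scan_panel(tibble::tibble(
#'   position = c(NA, 32, 33, NA, 32, 33),
#'   wt_aa = c("WT", "K", "A", "WT", "K", "A"),
#'   mut_aa = c("WT", "D", "D", "WT", "D", "D"),
#'   replicate = c(1, 1, 1, 2, 2, 2),
#'   expression_mfi = c(1000, 950, 1100, 980, 900, 1050),
#'   binding_mfi = c(500, 200, 480, 490, 210, 470)
#' ), sequence_window = c(31, 82))
#' score_panel(pan)
scan_panel <- function(records, sequence_window = NULL, ligand_conc = 1) {
  records <- as_tibble(records)
  required <- c("position", "wt_aa", "mut_aa", "replicate",
                "expression_mfi", "binding_mfi")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("scan table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "chargescan_validation")
  }
  records$position <- as.integer(records$position)
  records$replicate <- as.integer(records$replicate)
  is_wt <- records$mut_aa == "WT"
  if (is.null(sequence_window)) {
    if (!any(!is_wt)) {
      abort("scan table contains no mutant rows", class = "chargescan_validation")
    }
    sequence_window <- range(records$position[!is_wt])
  }
  sequence_window <- as.integer(sequence_window)
  panel <- new_tibble(records, class = "scan_panel",
                      sequence_window = sequence_window,
                      ligand_conc = as.numeric(ligand_conc))
  validate_scan_panel(panel)
  panel
}

#' Sequence window and probe concentration of a scan panel
#'
#' @param panel A `scan_panel`.
#' @return `sequence_window()`: integer length-2 vector (first, last residue).
#'   `ligand_conc()`: probe concentration in nM.
#' @export
sequence_window <- function(panel) attr(panel, "sequence_window")

#' @rdname sequence_window
#' @export
ligand_conc <- function(panel) attr(panel, "ligand_conc")

validate_scan_panel <- function(panel) {
  problems <- character()
  row_problem <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      sprintf("row %d: %s", which(rows), msg)
    } else character()
  }
  is_wt <- panel$mut_aa == "WT"
  problems <- c(
    problems,
    row_problem(!is_wt & (is.na(panel$position) | panel$position < 1L),
                "position must be a residue index >= 1"),
    row_problem(is.na(panel$expression_mfi) | panel$expression_mfi <= 0,
                "expression_mfi must be > 0"),
    row_problem(is.na(panel$binding_mfi) | panel$binding_mfi < 0,
                "binding_mfi must be >= 0"),
    row_problem(!is_wt & !is.na(panel$wt_aa) & panel$wt_aa == panel$mut_aa,
                "wt_aa must differ from mut_aa (or mut_aa = \"WT\")")
  )
  if ("ratio_mfi" %in% names(panel)) {
    problems <- c(problems,
                  row_problem(!is.na(panel$ratio_mfi) & panel$ratio_mfi < 0,
                              "ratio_mfi must be >= 0"))
  }
  win <- attr(panel, "sequence_window")
  problems <- c(
    problems,
    row_problem(!is_wt & !is.na(panel$position) &
                  (panel$position < win[1] | panel$position > win[2]),
                sprintf("position outside sequence window %d..%d", win[1], win[2]))
  )
  # duplicate (position, mut_aa, replicate) among mutant rows
  if (any(!is_wt)) {
    key <- paste(panel$position, panel$mut_aa, panel$replicate)[!is_wt]
    dup <- duplicated(key)
    if (any(dup)) {
      problems <- c(problems,
                    sprintf("duplicate record for (position, mut_aa, replicate) = (%s)",
                            unique(key[dup])))
    }
  }
  # WT reference coverage: one WT row per replicate seen in mutant rows
  reps <- sort(unique(panel$replicate[!is_wt]))
  wt_reps <- panel$replicate[is_wt]
  for (r in reps) {
    k <- sum(wt_reps == r)
    if (k == 0) {
      problems <- c(problems, sprintf("no WT reference for replicate %d", r))
    } else if (k > 1) {
      problems <- c(problems, sprintf("multiple WT reference rows for replicate %d", r))
    }
  }
  if (length(problems) > 0) {
    abort(c("invalid scan panel", problems), class = "chargescan_validation")
  }
  invisible(panel)
}

#' Read a scan table from CSV/TSV
#'
#' Expected columns: `position, wt_aa, mut_aa, replicate, expression_mfi,
#' binding_mfi[, ratio_mfi]`, with WT reference rows using `mut_aa = "WT"`.
#' Flow-cytometry software exports vary, so a `dialect` map can rename
#' arbitrary headers onto this canonical set.
#'
#' @param path Path to a `.csv` (comma) or `.tsv`/`.txt` (tab) file.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(position = "Residue", expression_mfi = "MFI_488")`.
#' @inheritParams scan_panel
#' @return A validated [scan_panel()].
#' @export
read_scan_table <- function(path, dialect = NULL, sequence_window = NULL,
                            ligand_conc = 1) {
  df <- read_delim_auto(path)
  if (!is.null(dialect)) {
    df <- dplyr::rename(df, !!!dialect)
  }
  df <- convert_columns(df,
                        double_cols = c("expression_mfi", "binding_mfi",
                                        "ratio_mfi"),
                        int_cols = c("position", "replicate"))
  scan_panel(df, sequence_window = sequence_window, ligand_conc = ligand_conc)
}

# columns are read as text and converted with base R's strtod-backed
# parsers, which are correctly rounded (numbers written with 17 significant
# digits then round-trip bit-exactly)
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "chargescan_validation")
  }
  df <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = "c"))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = "c"))
  }
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  df
}

# schema-driven conversion of a character-read table
convert_columns <- function(df, double_cols = character(),
                            int_cols = character()) {
  for (col in intersect(double_cols, names(df))) {
    v <- as.numeric(df[[col]])
    if (any(is.na(v) & !is.na(df[[col]]))) {
      abort(sprintf("column %s contains non-numeric entries", col),
            class = "chargescan_validation")
    }
    df[[col]] <- v
  }
  for (col in intersect(int_cols, names(df))) {
    df[[col]] <- as.integer(as.numeric(df[[col]]))
  }
  remaining <- setdiff(names(df), c(double_cols, int_cols))
  for (col in remaining) {
    df[[col]] <- utils::type.convert(df[[col]], as.is = TRUE)
  }
  df
}

#' Write a scan panel / titration / conservation table to disk
#'
#' Plain-text writers matching the corresponding readers; numeric values are
#' written with full round-trip precision so `read(write(x))` reproduces every
#' field bit-exactly.
#'
#' @param panel,curve,cons Object to write.
#' @param path Output path (`.csv` for scan tables and titrations, `.tsv` for
#'   conservation tables).
#' @return The input, invisibly.
#' @export
write_scan_table <- function(panel, path) {
  readr::write_csv(format_full_precision(as_tibble(panel)), path,
                   progress = FALSE)
  invisible(panel)
}

# render doubles with 17 significant digits so that parsing the text
# reproduces the binary value bit-exactly
format_full_precision <- function(df) {
  dplyr::mutate(df, across(
    dplyr::where(\(x) is.double(x) && !inherits(x, "integer64")),
    \(x) ifelse(is.na(x), NA_character_,
                ifelse(x == round(x) & abs(x) < 1e15,
                       sprintf("%.0f", x), sprintf("%.17g", x)))))
}

#' Construct a titration curve
#'
#' A binding titration of one displayed variant against a ligand concentration
#' series. Concentrations are ligand *dimer* concentrations in nM; rows are
#' re-sorted ascending.
#'
#' @param conc Ligand dimer concentrations in nM; strictly positive, no
#'   duplicates, at least 4 points.
#' @param binding_mfi Binding-channel MFI per concentration.
#' @param variant_id Label of the displayed variant (e.g. `"WT"`).
#' @return A tibble of class `titration_curve` with columns `conc` (nM) and
#'   `binding_mfi`, attribute `variant_id`.
#' @export
titration_curve <- function(conc, binding_mfi, variant_id = "WT") {
  if (length(conc) != length(binding_mfi)) {
    abort("conc and binding_mfi must have the same length",
          class = "chargescan_validation")
  }
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("non-positive concentration in titration", class = "chargescan_validation")
  }
  if (length(conc) < 4) {
    abort("titration needs at least 4 concentration points",
          class = "chargescan_validation")
  }
  o <- order(conc)
  conc <- conc[o]
  binding_mfi <- binding_mfi[o]
  if (any(diff(conc) <= 0)) {
    abort("concentrations must be strictly increasing (duplicates present)",
          class = "chargescan_validation")
  }
  new_tibble(tibble(conc = as.numeric(conc), binding_mfi = as.numeric(binding_mfi)),
             class = "titration_curve", variant_id = variant_id)
}

#' Read a titration table from CSV
#'
#' Expected columns `conc`, `binding_mfi` and optionally `unit` (one of
#' `fM, pM, nM, uM, mM, M`, per row); concentrations are converted to nM and
#' sorted ascending with their paired MFIs.
#'
#' @inheritParams read_scan_table
#' @param variant_id Variant label attached to the curve.
#' @return A validated [titration_curve()].
#' @export
read_titration <- function(path, variant_id = "WT") {
  df <- convert_columns(read_delim_auto(path),
                        double_cols = c("conc", "binding_mfi"))
  if (!all(c("conc", "binding_mfi") %in% names(df))) {
    abort("titration file needs columns conc, binding_mfi",
          class = "chargescan_validation")
  }
  conc <- as.numeric(df$conc)
  if ("unit" %in% names(df)) {
    conc <- conc * unit_to_nM(df$unit)
  }
  titration_curve(conc, as.numeric(df$binding_mfi), variant_id = variant_id)
}

unit_to_nM <- function(unit) {
  factors <- c(fM = 1e-6, pM = 1e-3, nM = 1, uM = 1e3, mM = 1e6, M = 1e9)
  bad <- setdiff(unique(unit), names(factors))
  if (length(bad) > 0) {
    abort(sprintf("unknown concentration unit(s): %s", paste(bad, collapse = ", ")),
          class = "chargescan_validation")
  }
  unname(factors[unit])
}

#' @rdname write_scan_table
#' @export
write_titration <- function(curve, path) {
  out <- tibble(conc = curve$conc, unit = "nM", binding_mfi = curve$binding_mfi)
  readr::write_csv(format_full_precision(out), path, progress = FALSE)
  invisible(curve)
}

#' Construct / read a per-position conservation table
#'
#' A ConSurf-style export of per-position evolutionary conservation: one row
#' per residue position with a finite `score` (percent conservation or grade).
#' Extra columns (e.g. per-residue amino-acid frequencies) are carried along
#' untouched.
#'
#' @param x Data frame with columns `position` and `score`.
#' @return A tibble of class `conservation_table`.
#' @export
conservation_table <- function(x) {
  x <- as_tibble(x)
  if (!all(c("position", "score") %in% names(x))) {
    abort("conservation table needs columns position, score",
          class = "chargescan_validation")
  }
  x$position <- as.integer(x$position)
  if (anyDuplicated(x$position)) {
    abort("conservation table has duplicated positions",
          class = "chargescan_validation")
  }
  if (any(!is.finite(x$score))) {
    abort("conservation scores must be finite", class = "chargescan_validation")
  }
  new_tibble(arrange(x, .data$position), class = "conservation_table")
}

#' @rdname conservation_table
#' @param path Path to a TSV file with columns `position`, `score`.
#' @export
read_conservation <- function(path) {
  conservation_table(convert_columns(read_delim_auto(path),
                                     double_cols = "score",
                                     int_cols = "position"))
}

#' @rdname write_scan_table
#' @export
write_conservation <- function(cons, path) {
  readr::write_tsv(format_full_precision(as_tibble(cons)), path, progress = FALSE)
  invisible(cons)
}
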