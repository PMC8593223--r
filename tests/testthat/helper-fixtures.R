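# in-code fixtures shared across test files

# minimal well-formed scan table: 3 mutants x 2 replicates + 1 WT row per
# replicate = 8 records
tiny_scan_df <- function() {
  tibble::tibble(
    position = c(NA, 32L, 33L, 36L, NA, 32L, 33L, 36L),
    wt_aa = c("WT", "K", "A", "R", "WT", "K", "A", "R"),
    mut_aa = c("WT", "D", "D", "D", "WT", "D", "D", "D"),
    replicate = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    expression_mfi = c(1000, 950, 1100, 980, 990, 960, 1080, 1010),
    binding_mfi = c(500, 200, 480, 100, 495, 210, 470, 95)
  )
}

# a score table built directly from per-position values (no WT row needed by
# the classification/periodicity stages)
score_table_of <- function(position, value, mut_aa = "D",
                           window = range(position), sd = 0) {
  stopifnot(length(value) == length(position))
  tb <- tibble::tibble(
    position = as.integer(position),
    wt_aa = "A",
    mut_aa = mut_aa,
    mfi_exp = 1,
    mfi_ratio_mean = value,
    mfi_ratio_sd = sd,
    n_replicates = 2L
  )
  structure(tb, class = c("score_table", class(tb)),
            sequence_window = as.integer(window))
}

# default study-condition ground truth (one helical interface segment 45-66)
default_truth <- function(...) ground_truth(...)

zero_noise_truth <- function(n_cells = 1000, ...) {
  ground_truth(noise = noise_free(), n_cells = n_cells, ...)
}
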