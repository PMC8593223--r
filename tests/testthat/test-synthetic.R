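test_that("ground truth validates its invariants", {
  expect_s3_class(ground_truth(), "ground_truth")
  expect_error(ground_truth(kd_wt = -1), "invalid ground truth")
  expect_error(ground_truth(n_cells = 10), "invalid ground truth")
  expect_error(synthetic_noise(bind_cv = -0.1), "noise scales")
})

test_that("mutational ddG follows the rectified helical-face sinusoid", {
  truth <- ground_truth(interface_segments = tibble::tibble(
    first = 45L, last = 66L, ddg_base = 1.2, ddg_amp = 1.8,
    period = 3.6, phase = 0.4))
  expect_equal(mutant_ddg(truth, 31), 0)
  expect_equal(mutant_ddg(truth, 70), 0)
  # independently coded evaluation of the formula over the segment
  pos <- 45:66
  oracle <- pmax(0, 1.2 + 1.8 * sin(2 * pi * pos / 3.6 + 0.4))
  expect_equal(mutant_ddg(truth, pos), oracle, tolerance = 1e-12)

  flat <- ground_truth(interface_segments = tibble::tibble(
    first = 45L, last = 66L, ddg_base = 1.5, ddg_amp = 0,
    period = 3.6, phase = 0))
  expect_equal(mutant_ddg(flat, 45:66), rep(1.5, 22))
})

test_that("identical seed and truth give bit-identical panels", {
  truth <- ground_truth(n_cells = 150)
  a <- simulate_scan_panel(truth, positions = 40:50, seed = 42)
  b <- simulate_scan_panel(truth, positions = 40:50, seed = 42)
  expect_identical(as.data.frame(a$panel), as.data.frame(b$panel))
  expect_identical(a$truth_labels, b$truth_labels)
  c_ <- simulate_scan_panel(truth, positions = 40:50, seed = 43)
  expect_false(identical(as.data.frame(a$panel), as.data.frame(c_$panel)))
})

test_that("zero-noise panels hit the closed-form bound-fraction ratios", {
  truth <- zero_noise_truth(n_cells = 300)
  sim <- simulate_scan_panel(truth, positions = c(35L, 50L), seed = 1)
  sc <- score_panel(sim$panel)
  # non-interface mutant: f_mut = f_wt -> ratio exactly 1
  expect_equal(sc$mfi_ratio_mean[sc$position %in% 35], 1.0, tolerance = 1e-12)

  # a huge penalty maps through f = L/(Kd+L); closed form, independently coded
  big <- ground_truth(noise = noise_free(), n_cells = 300,
                      interface_segments = tibble::tibble(
                        first = 50L, last = 50L, ddg_base = 10, ddg_amp = 0,
                        period = 3.6, phase = 0))
  sim2 <- simulate_scan_panel(big, positions = c(35L, 50L), seed = 2)
  sc2 <- score_panel(sim2$panel)
  L <- big$probe_conc
  kd_mut <- big$kd_wt * exp(10 / big$rt)
  expected <- (L / (kd_mut + L)) / (L / (big$kd_wt + L))
  expect_equal(sc2$mfi_ratio_mean[sc2$position %in% 50], expected,
               tolerance = 1e-9)
})

test_that("empirical scores converge to f_mut/f_wt as cells grow", {
  # expression spread and binding CV stay on; the additive autofluorescence
  # term is off because it biases the per-cell ratio by a fixed offset that
  # does not vanish with cell count
  truth <- ground_truth(n_cells = 1e5,
                        noise = synthetic_noise(autofluor_mean = 0,
                                                autofluor_sd = 0))
  sim <- simulate_scan_panel(truth, positions = c(40L, 50L, 55L), seed = 8)
  sc <- score_panel(sim$panel)
  mut <- dplyr::filter(sc, mut_aa != "WT") |>
    dplyr::left_join(sim$truth_labels, by = c("position", "wt_aa", "mut_aa"))
  f <- function(kd) truth$probe_conc / (kd + truth$probe_conc)
  expected <- f(mut$kd_true) / f(truth$kd_wt)
  expect_lt(max(abs(mut$mfi_ratio_mean - expected)), 0.01)
})

test_that("the helical ddG modulation leaves a spectral fingerprint", {
  # dominant Fourier period of the detrended score series over the interface
  dominant_period <- function(v) {
    n_pad <- 2048
    padded <- c(v - mean(v), rep(0, n_pad - length(v)))
    p <- Mod(stats::fft(padded))[2:(n_pad / 2)]
    freq <- (seq_along(p)) / n_pad
    keep <- freq >= 1 / 8 & freq <= 1 / 2 # periods between 2 and 8 residues
    1 / freq[keep][which.max(p[keep])]
  }
  truth <- ground_truth()
  periods <- purrr::map_dbl(1:50, function(s) {
    sim <- simulate_scan_panel(truth, positions = 38:73, seed = s,
                               substitutions = "D")
    ser <- score_panel(sim$panel) |> score_series() |> fill_missing() |>
      detrend(5)
    dominant_period(ser$corrected[ser$position >= 45 & ser$position <= 66])
  })
  expect_lt(abs(mean(periods) - 3.6), 0.2)
})

test_that("simulated titrations follow the one-site model with seeded noise", {
  truth <- zero_noise_truth()
  curve <- simulate_titration(truth, ddg = 0.8, seed = 5)
  kd_true <- truth$kd_wt * exp(0.8 / truth$rt)
  fit <- fit_one_site(curve)
  expect_equal(fit$kd, kd_true, tolerance = 1e-6)

  noisy <- ground_truth()
  wt1 <- simulate_titration(noisy, ddg = 0, seed = 7)
  wt2 <- simulate_titration(noisy, ddg = 0, seed = 7)
  expect_identical(as.data.frame(wt1), as.data.frame(wt2))
})
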