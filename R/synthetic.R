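#' Noise model for the synthetic yeast-display measurement process
#'
#' Defaults emulate a typical surface-display FACS experiment: per-cell
#' expression fluorescence log-normal around ~1000 a.u. with sigma 0.5 (the
#' usual order-of-magnitude cell-to-cell spread of display levels),
#' multiplicative binding-channel noise of 20% CV, a small additive
#' autofluorescence background, and a per-mutant biological "incidental"
#' ddG perturbation (sd 0.04 kcal/mol) reflecting that charged substitutions
#' outside the interface are not perfectly silent.
#'
#' @param expr_lognorm_mu,expr_lognorm_sigma Meanlog / sdlog of per-cell
#'   expression intensity.
#' @param bind_cv Multiplicative CV of the binding channel per cell.
#' @param autofluor_mean,autofluor_sd Additive autofluorescence (a.u.,
#'   floored at 0 per cell).
#' @param ddg_sd Per-mutant incidental binding ddG perturbation, kcal/mol.
#' @return A named list of noise parameters.
#' @export
synthetic_noise <- function(expr_lognorm_mu = log(1000),
                            expr_lognorm_sigma = 0.5,
                            bind_cv = 0.2,
                            autofluor_mean = 5,
                            autofluor_sd = 2,
                            ddg_sd = 0.04) {
  noise <- list(expr_lognorm_mu = expr_lognorm_mu,
                expr_lognorm_sigma = expr_lognorm_sigma,
                bind_cv = bind_cv,
                autofluor_mean = autofluor_mean,
                autofluor_sd = autofluor_sd,
                ddg_sd = ddg_sd)
  scales <- noise[c("expr_lognorm_sigma", "bind_cv", "autofluor_mean",
                    "autofluor_sd", "ddg_sd")]
  if (any(!vapply(noise, is.finite, logical(1))) ||
      any(unlist(scales) < 0)) {
    abort("all noise scales must be finite and >= 0",
          class = "chargescan_validation")
  }
  noise
}

#' @rdname synthetic_noise
#' @export
noise_free <- function() {
  synthetic_noise(expr_lognorm_sigma = 0.5, bind_cv = 0,
                  autofluor_mean = 0, autofluor_sd = 0, ddg_sd = 0)
}

#' Ground truth for the synthetic scanning-mutagenesis generator
#'
#' Defines the "true" system a synthetic experiment measures: the WT
#' dissociation constant, the interface segment(s) with their helical-face
#' ddG geometry, the probe concentration, the thermal energy used to map ddG
#' to Kd fold-changes, the noise model, and the experiment size.
#'
#' The default interface geometry is a single 22-residue segment (45-66) with
#' `ddg = max(0, 2 + 1.8 * sin(2*pi*position/3.6))` kcal/mol: an amphipathic
#' helix whose contact face carries hot-spot-scale penalties (up to 3.8
#' kcal/mol, the classic scanning-mutagenesis hot-spot range) while the
#' solvent face retains a small residual contribution (0.2 kcal/mol) -- a
#' bound helix keeps even its away-face residues near the partner, so no
#' interface position is strictly silent. This produces the continuum of
#' mutational effects these scans actually show while keeping the whole
#' interface detectable.
#'
#' @param kd_wt WT dissociation constant, nM (ligand dimer).
#' @param interface_segments Data frame with columns `first`, `last`,
#'   `ddg_base`, `ddg_amp` (kcal/mol), `period` (residues/cycle), `phase`
#'   (radians); one row per interface segment.
#' @param probe_conc Binding-stain ligand concentration, nM.
#' @param rt Thermal energy RT in kcal/mol (0.593 at 25 C).
#' @param noise A [synthetic_noise()] list.
#' @param n_cells Cells analysed per variant per replicate (>= 100).
#' @param n_replicates Biological replicates.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kd_wt = 1,
                         interface_segments = tibble(
                           first = 45L, last = 66L, ddg_base = 2,
                           ddg_amp = 1.8, period = 3.6, phase = 0),
                         probe_conc = 1,
                         rt = 0.593,
                         noise = synthetic_noise(),
                         n_cells = 10000,
                         n_replicates = 2) {
  seg <- as_tibble(interface_segments)
  ok <- kd_wt > 0 && probe_conc > 0 && rt > 0 && n_cells >= 100 &&
    n_replicates >= 1 &&
    all(c("first", "last", "ddg_base", "ddg_amp", "period", "phase") %in% names(seg)) &&
    all(seg$ddg_base >= 0) && all(seg$period > 0) && all(seg$last >= seg$first)
  if (!ok) {
    abort("invalid ground truth (need kd_wt > 0, probe_conc > 0, rt > 0, n_cells >= 100, ddg_base >= 0, period > 0)",
          class = "chargescan_validation")
  }
  structure(list(kd_wt = kd_wt, interface_segments = seg,
                 probe_conc = probe_conc, rt = rt, noise = noise,
                 n_cells = as.integer(n_cells),
                 n_replicates = as.integer(n_replicates)),
            class = "ground_truth")
}

#' True mutational binding ddG at a position
#'
#' Interface positions carry `ddg = max(0, ddg_base + ddg_amp *
#' sin(2*pi*position/period + phase))` kcal/mol -- a sinusoid along the
#' sequence, rectified at zero, encoding a helix with one face contacting the
#' partner. Non-interface positions carry 0.
#'
#' @param truth A [ground_truth()].
#' @param position Residue position(s).
#' @return ddG in kcal/mol (vectorized).
#' @export
mutant_ddg <- function(truth, position) {
  seg <- truth$interface_segments
  vapply(position, function(p) {
    hit <- which(seg$first <= p & p <= seg$last)
    if (length(hit) == 0) return(0)
    s <- seg[hit[1], ]
    max(0, s$ddg_base + s$ddg_amp * sin(2 * pi * p / s$period + s$phase))
  }, numeric(1))
}

fraction_bound <- function(kd, conc) conc / (kd + conc)

# one variant-replicate worth of per-cell measurement, summarized to MFIs
simulate_variant_mfis <- function(truth, f) {
  ns <- truth$noise
  n <- truth$n_cells
  expr <- rlnorm(n, ns$expr_lognorm_mu, ns$expr_lognorm_sigma)
  eps <- if (ns$bind_cv > 0) rnorm(n, 0, ns$bind_cv) else numeric(n)
  af <- if (ns$autofluor_mean > 0 || ns$autofluor_sd > 0) {
    pmax(0, rnorm(n, ns$autofluor_mean, ns$autofluor_sd))
  } else numeric(n)
  bind <- pmax(0, f * expr * (1 + eps) + af)
  c(expression_mfi = mean(expr), binding_mfi = mean(bind),
    ratio_mfi = mean(bind / expr))
}

#' Simulate a charged-residue scan panel with recorded ground truth
#'
#' Emulates the full measurement chain: each mutant's true Kd is
#' `kd_wt * exp(ddg/RT)` with `ddg` the interface geometry of `truth` plus a
#' per-mutant incidental perturbation (`noise$ddg_sd`); its fraction bound at
#' the probe concentration is `[L]/(Kd+[L])`; per cell, binding fluorescence
#' is fraction-bound x expression with multiplicative noise plus
#' autofluorescence; per variant and replicate the per-cell draws are
#' summarized to expression, binding and mean per-cell-ratio MFIs. WT
#' reference rows are included per replicate. Identical seed and truth give
#' bit-identical panels.
#'
#' @param truth A [ground_truth()].
#' @param positions Residue positions scanned.
#' @param substitutions Substituting residue(s), e.g. `"D"` or `c("D", "R")`.
#' @param seed Integer seed (the generator is restored afterwards).
#' @return A list: `panel` (a [scan_panel()]), `truth_labels` (tibble with
#'   `position`, `mut_aa`, `ddg_true`, `kd_true`, `interface` flag), and
#'   `truth` (the input, echoed).
#' @export
simulate_scan_panel <- function(truth, positions = 31:82,
                                substitutions = "D", seed = 1) {
  withr::local_seed(seed)
  seg <- truth$interface_segments
  aa_pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], substitutions)
  wt_seq <- sample(aa_pool, length(positions), replace = TRUE)

  design <- tidyr::expand_grid(position = as.integer(positions),
                               mut_aa = substitutions) |>
    arrange(.data$position, .data$mut_aa)
  design$wt_aa <- wt_seq[match(design$position, positions)]
  ddg_geom <- mutant_ddg(truth, design$position)
  eta <- if (truth$noise$ddg_sd > 0) {
    rnorm(nrow(design), 0, truth$noise$ddg_sd)
  } else numeric(nrow(design))
  design$ddg_true <- ddg_geom + eta
  design$kd_true <- truth$kd_wt * exp(design$ddg_true / truth$rt)
  design$interface <- purrr::map_lgl(design$position, function(p)
    any(seg$first <= p & p <= seg$last))

  f_wt <- fraction_bound(truth$kd_wt, truth$probe_conc)
  f_mut <- fraction_bound(design$kd_true, truth$probe_conc)

  rows <- vector("list", truth$n_replicates * (nrow(design) + 1))
  k <- 0
  for (rep_i in seq_len(truth$n_replicates)) {
    m <- simulate_variant_mfis(truth, f_wt)
    k <- k + 1
    rows[[k]] <- tibble(position = NA_integer_, wt_aa = "WT", mut_aa = "WT",
                        replicate = rep_i,
                        expression_mfi = m[["expression_mfi"]],
                        binding_mfi = m[["binding_mfi"]],
                        ratio_mfi = m[["ratio_mfi"]])
    for (j in seq_len(nrow(design))) {
      m <- simulate_variant_mfis(truth, f_mut[j])
      k <- k + 1
      rows[[k]] <- tibble(position = design$position[j],
                          wt_aa = design$wt_aa[j],
                          mut_aa = design$mut_aa[j],
                          replicate = rep_i,
                          expression_mfi = m[["expression_mfi"]],
                          binding_mfi = m[["binding_mfi"]],
                          ratio_mfi = m[["ratio_mfi"]])
    }
  }
  panel <- scan_panel(bind_rows(rows),
                      sequence_window = range(positions),
                      ligand_conc = truth$probe_conc)
  list(panel = panel,
       truth_labels = select(design, "position", "wt_aa", "mut_aa",
                             "ddg_true", "kd_true", "interface"),
       truth = truth)
}

#' Simulate a binding titration for one variant
#'
#' `MFI([L]) = Bmax * [L] / (Kd + [L]) * (1 + eps)` with `Kd = kd_wt *
#' exp(ddg/RT)` and multiplicative noise `eps ~ N(0, noise$bind_cv)` per
#' point.
#'
#' @inheritParams simulate_scan_panel
#' @param ddg Variant binding ddG in kcal/mol (0 = WT).
#' @param concentrations Ligand dimer concentrations in nM.
#' @param bmax Saturating MFI.
#' @param variant_id Label for the curve.
#' @return A [titration_curve()].
#' @export
simulate_titration <- function(truth, ddg = 0,
                               concentrations = titration_design(),
                               bmax = 1000, seed = 1, variant_id = "WT") {
  withr::local_seed(seed)
  kd <- truth$kd_wt * exp(ddg / truth$rt)
  eps <- if (truth$noise$bind_cv > 0) {
    rnorm(length(concentrations), 0, truth$noise$bind_cv)
  } else numeric(length(concentrations))
  mfi <- bmax * fraction_bound(kd, concentrations) * (1 + eps)
  titration_curve(concentrations, mfi, variant_id = variant_id)
}
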