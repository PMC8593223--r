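# chargescan

Charged-residue scanning mutagenesis analysis for mapping the binding
interface — and inferring the bound-state local structure — of intrinsically
disordered proteins (IDPs), from yeast-surface-display flow-cytometry data.

Many IDPs, such as bacterial type II antitoxins, fold only upon binding their
partner. A fast route to their interface is to substitute each residue of the
candidate region with a charged amino acid (aspartate, arginine), display each
variant on yeast, and read expression and partner binding per variant by FACS.
`chargescan` implements the full computational path from the exported
per-mutant mean fluorescence intensities (MFIs) to interface calls, local
secondary structure, and dissociation constants, plus a synthetic-data
generator with recorded ground truth so the entire pipeline is testable
without any external dataset.

## The quantities computed

- **Normalized scores.** Per mutant,
  `MFI_exp = expression MFI (mutant) / expression MFI (WT)` and
  `MFI_ratio = mean binding:expression ratio MFI (mutant) / same for WT`,
  normalized per biological replicate against that replicate's own WT
  reference, then averaged (mean ± sd, n−1) across replicates. WT scores 1
  by construction; lower `MFI_ratio` means binding-defective.
- **Interface calls.** Aspartate-substitution scores are partitioned by
  *exact* 1-D two-means clustering (globally optimal sorted-split search —
  no Lloyd iteration, no seed). The binding-defective cutoff is
  `mean(class 1) − sd(class 1)`, where class 1 is the WT-like class; a
  position is called if any charged substitution there scores strictly below
  the cutoff.
- **Local structure from periodicity.** The per-position Asp score series is
  detrended by subtracting a 5-residue sliding-window mean, and each residue
  segment is fitted with `y = a·sin(2πx/b + c)`. A fitted periodicity
  `b ≈ 3.6` residues/cycle is the canonical α-helical repeat (one helix face
  contacting the partner); `b ≈ 2` indicates strand-like register. For fixed
  `b` the model is linear in amplitude and phase, so the fit profiles `b`
  over a dense grid — deterministic and globally optimal over the range.
- **Dissociation constants.** Titration curves are fitted with the one-site
  hyperbola `MFI = Bmax·[L]/(Kd + [L])` ([L] = ligand dimer concentration,
  nM), and an ordinary least-squares line `Kd = slope·MFI_ratio + intercept`
  through reference variants serves as an internal standard mapping scores of
  unmeasured mutants to apparent Kd.
- **Conservation.** Per-position scores are joined to a ConSurf-style
  conservation table; Pearson and Spearman correlations are reported.
- **Synthetic truth.** The generator draws per-cell log-normal expression,
  binding = fraction-bound × expression with multiplicative noise plus
  autofluorescence, with mutant Kd shifts `Kd_mut = Kd_wt·exp(ΔΔG/RT)` from a
  rectified sinusoidal ΔΔG profile over the interface segment (the
  helical-face geometry).

## Worked example

Simulate a 52-position aspartate scan (positions 31–82, two replicates,
10,000 cells per variant) whose true interface is a helical segment at
residues 45–66, then run the stages:

```r
library(chargescan)

truth  <- ground_truth()                  # Kd_wt = 1 nM, helix 45-66, period 3.6
sim    <- simulate_scan_panel(truth, positions = 31:82, seed = 42)
scores <- score_panel(sim$panel)

classify_interface(scores)
#> Two-class partition of 52 D-substitution scores
#>   class 1 (WT-like):            mean 0.966, sd 0.111
#>   class 2 (binding-defective):  mean 0.095, sd 0.124
#>   threshold (mean1 - sd1):      0.855
#>   interface calls: 22 position(s)
#>     45, 46, 47, 48, ..., 65, 66

series <- scores |> score_series() |> fill_missing() |> detrend(window = 5)
fit_segments(series, breakpoints = c(45, 67)) |> tidy()
#> # A tibble: 3 x 10
#>   first  last      a     b     c   se_b     r    sse     n label
#> 1    31    44 0.0535  7.46  2.75 1.27   0.552 0.0616    14 irregular/ambiguous
#> 2    45    66 0.459   3.56  2.01 0.0314 0.918 0.450     22 alpha-helix
#> 3    67    82 0.0725  5.25  2.57 0.490  0.497 0.146     16 irregular/ambiguous
```

All 22 true interface positions are called and only those; the fitted
periodicity of the interface segment, 3.56 ± 0.03 residues/cycle, recovers
the canonical α-helical repeat (3.6), while the flanking segments —
ΔΔG-silent in the ground truth — show low-amplitude, low-correlation fits
and stay unassigned. A titration of a simulated mutant
(ΔΔG = 0.8 kcal/mol, true Kd = 3.86 nM):

```r
fit_one_site(simulate_titration(truth, ddg = 0.8, seed = 1, variant_id = "I50D"))
#> One-site binding fit [I50D]: Bmax = 922.4, Kd = 2.917 +/- 1.3 nM, SSE = 2.282e+05
```

`run_pipeline(run_config(...))` orchestrates all stages on one configuration
and writes auditable CSV/JSON intermediates; `autoplot()` methods exist for
score tables, classifications, segment fits, binding fits and conservation
reports, and `tidy()`/`glance()` for every fitted object.

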