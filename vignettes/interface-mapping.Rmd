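---
title: "Mapping a disordered protein's binding interface from charged-residue scanning data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a disordered protein's binding interface from charged-residue scanning data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(chargescan)
```

## The measurement and its model

A charged-residue scan probes, position by position, how much each residue of
a candidate binding region contributes to a protein–protein interaction.
Each single substitution (aspartate throughout the region, arginine at a
subset) is displayed on the yeast surface; flow cytometry reads two channels
per cell — surface expression and binding of the labelled partner. The
package consumes the per-variant summaries of those channels (mean
fluorescence intensities, MFIs) and works with two normalized scores:

* `MFI_exp` — mutant expression MFI over WT expression MFI. It verifies that
  a binding defect is not an expression artefact; it plays no further role in
  the pipeline because charged substitutions in a displayed disordered region
  rarely perturb display levels.
* `MFI_ratio` — the mutant's mean per-cell binding:expression fluorescence
  ratio over the WT's, computed within each biological replicate against that
  replicate's own WT reference, then averaged across replicates (sd with the
  n−1 denominator; with two replicates this equals |x₁−x₂|/√2).

Two conventions here were genuinely open and are worth stating. First,
normalization is per replicate, not against a pooled WT: instrument gain and
staining efficiency drift between experiments, and dividing within a
replicate cancels any per-channel rescaling exactly (this invariance is
tested). Second, the per-cell ratio is averaged ("mean of ratios"), not the
ratio of channel means; with per-cell data the two differ whenever expression
and binding covary. When only summary MFIs are available the supplied ratio
column is trusted as exported; if absent, the record-level
`binding_mfi/expression_mfi` is the fallback. A mutant with zero binding
signal scores 0 — a valid measurement, not an error.

Under the one-site picture the expected per-cell ratio is proportional to the
fraction of displayed protein bound at probe concentration `[L]`:
`f = [L]/(Kd + [L])`, so `MFI_ratio ≈ f_mut/f_wt`. This is the link that
makes the score quantitative and is what the synthetic generator encodes.

## Interface calls: exact two-means and the mean−sd cutoff

Aspartate scores across the scanned window are bimodal-ish: a WT-like class
and a binding-defective class. The partition uses the k-means objective with
k fixed at 2, but computed exactly: in one dimension the optimal two
clusters are contiguous in sorted order, so scanning the n−1 sorted split
points (with prefix sums) finds the global optimum deterministically. Lloyd
iteration would add a dependence on starting centers for no benefit; the
exactness is itself tested against a brute-force oracle up to n = 1000 and
against `stats::kmeans` with many restarts.

The binding-defective cutoff is `mean(class 1) − sd(class 1)`, class 1 being
the WT-like (larger-mean) class. The cutoff is *derived* from aspartate
scores only but *applied* to both aspartate and arginine substitutions
("strictly below": ties are not called), so positions lacking an Asp mutant
are callable from Arg data alone. Positions with no charged substitution at
all are reported as *uncovered*, never as negative. Lowering any score can
only add calls (monotonicity), which is tested.

## Local structure from periodicity

If the bound segment is a helix with one face against the partner, mutational
effects oscillate along the sequence with the helical repeat. Two steps
expose this:

1. **Detrending.** The per-position Asp score series (positions with no Asp
   data are filled with the WT value 1.0 and flagged) is corrected by
   subtracting its mean over a `window`-residue sliding window. The default
   window is 5 residues (~1.4 helical turns): wide enough to estimate the
   local baseline, short enough to preserve phase changes; windows of 5–11
   give the same periodicities on smooth profiles, and window equivalence
   against a naively coded sliding mean is tested for all four widths. At
   the series edges the window truncates rather than shortening the series,
   so every scanned position keeps a corrected value.
2. **Sinusoid fitting.** Each segment is fitted with `y = a·sin(2πx/b + c)`,
   `x` the absolute residue index. For fixed `b` the model is *linear* in
   `(a·cos c, a·sin c)`, so amplitude and phase have an exact least-squares
   solution and only the periodicity needs searching: `b` is profiled on a
   dense grid over [2, 8] residues/cycle (strand register through loose
   helix; step 0.02) and refined by 1-D optimization around the grid
   minimum. This replaces the more usual multi-start nonlinear refinement:
   it is deterministic, cannot miss the global optimum in the two linear
   parameters, and matches a dense brute-force (a, b, c) grid search within
   1e-6 in SSE (tested). Amplitude is reported ≥ 0 with phase in [0, 2π)
   via the (−a, c) ≡ (a, c+π) equivalence; `r` is the Pearson correlation
   between observed and fitted values, and parameter standard errors are the
   usual asymptotic (Jacobian-based) estimates.

Segment boundaries can be given manually (the reproduction mode — phase
changes are usually visible by eye) or searched exhaustively
(`scan_breakpoints`, up to two breakpoints, minimum segment 8 residues)
under a small-sample AICc penalty (3 parameters per segment + noise
variance) so that extra segments must reduce SSE enough to pay for
themselves; ties prefer fewer, then later, breakpoints. The single-segment
fit is always reported alongside for comparison.

Interpretation maps periodicity to structure: `3.2 ≤ b ≤ 4.1` is labelled
α-helical (canonical 3.6 residues/turn), `1.8 ≤ b ≤ 2.2` strand-like,
anything else irregular/ambiguous. Labels come with the fitted uncertainty
of `b`; a low-amplitude, low-`r` fit should not be over-read regardless of
its `b`.

## Dissociation constants and the internal standard

Titrations of displayed variants against the purified partner (ligand
*dimer* concentrations, internally always nM) are fitted by nonlinear least
squares to the one-site hyperbola `MFI = Bmax·[L]/(Kd + [L])`, with
deterministic initialization (`Bmax₀` = max MFI; `Kd₀` = concentration
nearest half-max). The textbook hyperbola is used deliberately: it is the
model the "one-site ligand binding" name denotes, it is bounded by `Bmax`,
strictly increasing in `[L]`, and exactly half-saturated at `[L] = Kd` (all
tested). Fitting is against concentration itself; plotting on a log axis is
presentation only. A fit whose highest probed concentration is below
`Kd/10` is flagged "poorly constrained" rather than trusted, and a flat
curve is an error. An optional additive baseline exists for MFIs that are
not autofluorescence-subtracted; the default assumes they are.

Reference variants with both a score and a fitted Kd define the internal
standard `Kd = slope·MFI_ratio + intercept` (ordinary least squares, ≥ 3
pairs). Since higher scores mean tighter binding the slope is negative. The
line is an honest *local* calibration: `f/f_wt` is not globally linear in
Kd, so the standard is most meaningful across the moderate-affinity range the
reference set spans, and apparent-Kd predictions below a configurable floor
are clamped and flagged rather than reported as non-physical values.

## Conservation

Per-position scores are inner-joined with a precomputed ConSurf-style
conservation table; Pearson and Spearman coefficients are both reported
because neither is canonical for this comparison and they respond
differently to outliers and monotone rescaling. The package does not build
alignments or run conservation servers; the table is an input.

## What the synthetic generator emulates — and what it does not

`ground_truth()` fixes the "true" system; `simulate_scan_panel()` then
emulates the measurement per cell: expression ~ LogNormal(μ = log 1000,
σ = 0.5) (the order-of-magnitude cell-to-cell spread of display levels);
binding = fraction-bound × expression × (1 + ε), ε ~ N(0, 0.2) (binding-stain
CV); plus additive autofluorescence N(5, 2) floored at 0; 10,000 cells per
variant per replicate and two biological replicates, summarized exactly as
the scoring stage expects. Mutant Kds follow `Kd_mut = Kd_wt·exp(ΔΔG/RT)`
with RT = 0.593 kcal/mol (25 °C). Probe concentration and `Kd_wt` both
default to 1 nM — staining near the WT Kd maximizes the dynamic range of the
ratio score, which is how such experiments are designed.

The interface geometry is a rectified sinusoid,
`ΔΔG(p) = max(0, ddg_base + ddg_amp·sin(2πp/period + phase))`, one helical
segment at residues 45–66 by default with `ddg_base = 2`, `ddg_amp = 1.8`
kcal/mol, period 3.6, phase 0. The contact face thus carries up to 3.8
kcal/mol (classic hot-spot magnitudes) while the solvent face retains a
small residual 0.2 kcal/mol: a bound helix keeps even its away-face residues
near the partner, so no interface position is strictly silent. This choice
makes the whole interface detectable in principle, matching the design
premise of the assay; with a fully rectified geometry (`amp = base`) the
integer-position sampling can leave 2–3 residues of a genuine interface
indistinguishable from WT, a realistic pathology worth exploring via the
`interface_segments` argument but not a sensible default for a generator
whose purpose is end-to-end validation. Two further generator terms are
deliberate extensions beyond the minimal measurement model: a per-mutant
"incidental" ΔΔG perturbation (sd 0.04 kcal/mol) because real charged
substitutions outside the interface are not perfectly neutral — without it
the WT-like class would be unrealistically tight — and the autofluorescence
offset, which introduces the small positive bias real ratio scores carry
(the expected-value convergence test therefore switches it off).

Not emulated: cytometer artefacts that gating removes (doublets, spillover),
sorting/enrichment, per-cell correlation between staining channels beyond
the shared expression factor, and day-scale drift between replicates beyond
what per-replicate normalization cancels. Passing the synthetic recovery
tests therefore shows the *computational* chain is correct and calibrated
under the stated noise model — not that real cytometry satisfies that model.

## Numerical choices and degenerate inputs

* Two-means requires ≥ 2 distinct values ("degenerate clustering" otherwise);
  a single-member class has sd 0, making the cutoff equal the class mean.
* Sinusoid fits require ≥ 6 residues; constant segments yield `a ≈ 0` with
  undefined `r` (NA) rather than an error.
* `fill_missing` on a series with no measured positions warns and returns
  the flat WT series.
* Readers parse numerics via base R's correctly-rounded `strtod`; writers
  render doubles with 17 significant digits, so every table round-trips
  bit-exactly through its CSV/TSV form.
* All simulation is seeded through `withr::local_seed`, so identical seeds
  give bit-identical panels without touching the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises the study-scale configuration where the property demands
it and smaller panels elsewhere: 52-position panels at 10,000 cells for the
periodicity-recovery (50 seeds) and interface-recovery (20 seeds) checks;
10–20-position panels at a few hundred cells for I/O, scoring and
invariance properties; 100,000 cells for the law-of-large-numbers check;
16-point titrations throughout, with 50–100 noise replicates for Kd
recovery. The full suite runs in about a minute on one core.

## Known limitations

* The mean−sd cutoff is a heuristic, not an error-rate guarantee; with a
  purely Gaussian WT-like class it will call its lower tail. Its usefulness
  rests on the defective class being well separated, which the clustering
  statistics let the user inspect.
* Periodicity inference assumes an additively decomposable profile (slow
  regional trend + fast helical modulation); strongly irregular interfaces
  can mask or distort the repeat, and WT-filled positions slightly flatten
  it (they are flagged so fits can exclude them).
* The Kd calibration is linear over a nonlinear underlying relation; treat
  apparent Kds far outside the reference range as order-of-magnitude
  estimates.
* Arginine and aspartate substitutions are treated symmetrically by the call
  rule; charge-specific effects (salt bridges broken vs formed) are not
  modelled.
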