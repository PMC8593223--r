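#' Fit a one-site ligand-binding isotherm
#'
#' Nonlinear least squares of the one-site binding hyperbola
#' `MFI = Bmax * [L] / (Kd + [L])` to a titration curve, with deterministic
#' initialization (`Bmax0` = max MFI, `Kd0` = concentration nearest
#' half-maximal signal). Concentrations are ligand dimer concentrations in nM;
#' the fitted `Kd` is in the same unit, so fitting in other units rescales
#' `Kd` by exactly the unit factor. An optional additive baseline is available
#' for MFIs that are not autofluorescence-subtracted.
#'
#' If the highest concentration probed is below `Kd/10` the curve never
#' approaches saturation and the fit is flagged `poorly_constrained`.
#'
#' @param curve A [titration_curve()] (>= 4 points; the concentration series
#'   should span at least two orders of magnitude).
#' @param offset If `TRUE`, fit `MFI = b0 + Bmax*[L]/(Kd+[L])`.
#' @return An object of class `binding_fit` with `bmax`, `kd` (nM), standard
#'   errors, `residual_sse`, `poorly_constrained`, `variant_id` and the data
#'   with fitted values. Has `tidy()`, `glance()`, `print()`, `predict()` and
#'   `autoplot()` methods.
#' @export
fit_one_site <- function(curve, offset = FALSE) {
  conc <- curve$conc
  mfi <- curve$binding_mfi
  if (length(conc) < 4) {
    abort("need at least 4 titration points", class = "chargescan_validation")
  }
  if (diff(range(mfi)) <= 1e-12 * max(abs(mfi), 1)) {
    abort("degenerate flat titration curve: binding MFI does not vary",
          class = "chargescan_validation")
  }
  bmax0 <- max(mfi)
  kd0 <- conc[which.min(abs(mfi - bmax0 / 2))]
  dat <- data.frame(conc = conc, mfi = mfi)
  fit <- if (offset) {
    minpack.lm::nlsLM(mfi ~ b0 + bmax * conc / (kd + conc), data = dat,
                      start = list(b0 = min(mfi), bmax = bmax0, kd = kd0),
                      lower = c(-Inf, 1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(mfi ~ bmax * conc / (kd + conc), data = dat,
                      start = list(bmax = bmax0, kd = kd0),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(co)),
                                                     names(co)))
  poorly <- max(conc) < co[["kd"]] / 10
  if (poorly) {
    warn(sprintf("Kd poorly constrained: max concentration %.3g nM < Kd/10 (Kd = %.3g nM)",
                 max(conc), co[["kd"]]))
  }
  fitted <- predict(fit)
  structure(
    list(bmax = co[["bmax"]], kd = co[["kd"]],
         b0 = if (offset) co[["b0"]] else 0,
         se_bmax = se[["bmax"]], se_kd = se[["kd"]],
         residual_sse = sum((mfi - fitted)^2),
         poorly_constrained = poorly,
         variant_id = attr(curve, "variant_id") %||% NA_character_,
         offset = offset,
         data = tibble(conc = conc, binding_mfi = mfi, fitted = fitted)),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("One-site binding fit%s: Bmax = %.4g, Kd = %.4g +/- %.2g nM, SSE = %.4g%s\n",
              if (!is.na(x$variant_id)) paste0(" [", x$variant_id, "]") else "",
              x$bmax, x$kd, x$se_kd, x$residual_sse,
              if (x$poorly_constrained) " (Kd poorly constrained)" else ""))
  invisible(x)
}

#' @rdname fit_one_site
#' @param x,object A `binding_fit`.
#' @param ... Unused.
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("bmax", "kd"),
         estimate = c(x$bmax, x$kd),
         std.error = c(x$se_bmax, x$se_kd))
}

#' @rdname fit_one_site
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(variant_id = x$variant_id, bmax = x$bmax, kd = x$kd,
         se_kd = x$se_kd, residual_sse = x$residual_sse,
         poorly_constrained = x$poorly_constrained, n = nrow(x$data))
}

#' @rdname fit_one_site
#' @param newdata Optional data frame with a `conc` column (nM).
#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc
  object$b0 + object$bmax * conc / (object$kd + conc)
}

#' Calibrate binding scores to apparent dissociation constants
#'
#' Ordinary least-squares line `Kd = slope * mfi_ratio + intercept` through
#' reference variants with both a normalized binding score and an
#' experimentally fitted Kd. The line serves as an internal standard mapping
#' scores of unmeasured mutants to apparent Kd values; since higher scores
#' mean tighter binding, the slope is expected to be negative.
#'
#' @param pairs A data frame with columns `mfi_ratio` and `kd` (nM), one row
#'   per reference variant; at least 3 rows.
#' @return An object of class `kd_calibration` with `slope`, `intercept`, `r`
#'   (Pearson correlation of the pairs), `n`, and the underlying `lm` model.
#' @export
calibrate_kd <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (!all(c("mfi_ratio", "kd") %in% names(pairs))) {
    abort("pairs needs columns mfi_ratio, kd", class = "chargescan_validation")
  }
  pairs <- filter(pairs, is.finite(.data$mfi_ratio), is.finite(.data$kd))
  if (nrow(pairs) < 3) {
    abort("need at least 3 reference (mfi_ratio, kd) pairs",
          class = "chargescan_validation")
  }
  m <- lm(kd ~ mfi_ratio, data = pairs)
  structure(
    list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
         r = cor(pairs$mfi_ratio, pairs$kd), n = nrow(pairs),
         model = m, pairs = pairs),
    class = "kd_calibration"
  )
}

#' @export
print.kd_calibration <- function(x, ...) {
  cat(sprintf("Kd calibration on %d reference variants: Kd = %.4g * mfi_ratio + %.4g nM (r = %.3f)\n",
              x$n, x$slope, x$intercept, x$r))
  invisible(x)
}

#' @rdname calibrate_kd
#' @param x A `kd_calibration`.
#' @param ... Unused.
#' @export
tidy.kd_calibration <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(summary(x$model)$coefficients[, "Std. Error"]))
}

#' @rdname calibrate_kd
#' @export
glance.kd_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r, n = x$n,
         sigma = summary(x$model)$sigma)
}

#' Apparent Kd from a calibrated score
#'
#' Evaluates the calibration line at given binding scores. Kd is a positive
#' quantity but the line is not constrained through the origin, so very high
#' scores can map below zero; such values are clamped to `floor` and flagged.
#'
#' @param calibration A [calibrate_kd()] result.
#' @param mfi_ratio Normalized binding score(s).
#' @param floor Lower clamp for the returned Kd, in nM.
#' @return A tibble with `mfi_ratio`, `kd_nM` and `clamped`.
#' @export
apparent_kd <- function(calibration, mfi_ratio, floor = 1e-3) {
  pred <- calibration$intercept + calibration$slope * mfi_ratio
  clamped <- pred < floor
  if (any(clamped)) {
    warn(sprintf("%d apparent Kd value(s) fell below the %.3g nM floor and were clamped",
                 sum(clamped), floor))
  }
  tibble(mfi_ratio = mfi_ratio, kd_nM = pmax(pred, floor), clamped = clamped)
}

#' Log-spaced titration concentration design
#'
#' The default 16-point ligand dimer concentration series spanning
#' 3.5e-5 nM (35 fM) to 500 nM.
#'
#' @param n Number of concentrations.
#' @param from,to Range in nM.
#' @return Numeric vector of concentrations in nM, ascending.
#' @export
titration_design <- function(n = 16, from = 3.5e-5, to = 500) {
  exp(seq(log(from), log(to), length.out = n))
}
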