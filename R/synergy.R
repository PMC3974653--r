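#' Fit the median-effect line to dose/fraction-affected data
#'
#' Chou-Talalay median-effect model: `fa/fu = (D/Dm)^m`, log-linear as
#' `log10(fa/(1-fa)) = m*log10(D) - m*log10(Dm)`. Parameters by least
#' squares on the log-linearized line; `r` is the line's linear correlation
#' coefficient. Fraction-affected values are clipped into
#' `[1e-6, 1 - 1e-6]` with a warning when clipping occurs.
#'
#' @param doses positive doses (at least 2 distinct).
#' @param fa fraction affected at each dose.
#' @return list of class `median_effect_fit`: dm (median-effect dose, input
#'   units), m (sigmoidicity), r.
#' @export
fit_median_effect <- function(doses, fa) {
  if (length(doses) != length(fa)) stop_input("unequal dose/fa lengths")
  if (any(doses <= 0)) stop_input("doses must be positive")
  if (length(unique(doses)) < 2) stop_input("need at least 2 distinct doses")
  eps <- 1e-6
  if (any(fa < eps | fa > 1 - eps)) {
    warning("fraction-affected values clipped into [1e-6, 1 - 1e-6]")
    fa <- pmin(pmax(fa, eps), 1 - eps)
  }
  if (length(unique(fa)) < 2)
    stop_input("degenerate fit: all fraction-affected values identical")
  x <- log10(doses)
  y <- log10(fa / (1 - fa))
  co <- stats::coef(stats::lm(y ~ x))
  m <- unname(co[2])
  if (!is.finite(m) || m == 0) stop_input("degenerate median-effect slope")
  structure(list(dm = 10^(-unname(co[1]) / m), m = m, r = stats::cor(x, y)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("median-effect fit: Dm = %.4g, m = %.4g, r = %.4f\n",
              x$dm, x$m, x$r))
  invisible(x)
}

#' Back-derive a median-effect fit from a printed DRI column
#'
#' In a constant-ratio combination report, each row's dose-reduction index
#' implies the single-drug dose `Dx = DRI * dose` producing that row's
#' effect. Fitting the median-effect line through the implied (Dx, fa)
#' points recovers the single-drug parameters the original analysis used,
#' without access to the raw single-drug curves.
#'
#' @param doses the drug's doses in the combination rows.
#' @param dri the printed dose-reduction indices.
#' @param fa the rows' fraction affected.
#' @return a `median_effect_fit`.
#' @export
median_effect_from_dri <- function(doses, dri, fa) {
  stopifnot(length(doses) == length(dri), length(dri) == length(fa))
  if (any(dri <= 0)) stop_input("dose-reduction indices must be positive")
  fit_median_effect(doses * dri, fa)
}

#' Dose producing a given effect under a median-effect fit
#'
#' `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a `median_effect_fit`.
#' @param fa fraction affected, strictly inside (0, 1); vectorized.
#' @export
equivalent_dose <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) stop_input("fa must lie strictly in (0, 1)")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Combination index of a dose pair
#'
#' Mutually exclusive Chou-Talalay form: `ci = dose1/Dx1 + dose2/Dx2`,
#' where `Dx_k` is the single-drug dose of drug k producing the pair's
#' effect level.
#'
#' @param dose1,dose2 actual doses in the combination.
#' @param dx1,dx2 single-drug equivalent doses at the same effect.
#' @export
combination_index <- function(dose1, dose2, dx1, dx2) {
  if (any(c(dx1, dx2) <= 0)) stop_input("equivalent doses must be positive")
  dose1 / dx1 + dose2 / dx2
}

#' Classify a combination index
#'
#' Additivity band 0.8-1.2; synergism below 0.8; antagonism above 1.2.
#'
#' @param ci combination index (vectorized).
#' @param bands lower/upper additivity bounds.
#' @return `"synergistic"`, `"additive"` or `"antagonistic"`.
#' @export
classify_ci <- function(ci, bands = c(0.8, 1.2)) {
  if (any(ci <= 0)) stop_input("combination index must be positive")
  ifelse(ci < bands[1], "synergistic",
         ifelse(ci > bands[2], "antagonistic", "additive"))
}

#' Dose-reduction index
#'
#' Fold reduction of a drug's dose achievable in combination at the same
#' effect level: `dri = Dx / dose`.
#'
#' @param dose actual dose in the combination (> 0).
#' @param dx single-drug equivalent dose at the effect level.
#' @export
dose_reduction_index <- function(dose, dx) {
  if (any(dose <= 0)) stop_input("doses must be positive")
  dx / dose
}

#' Full constant-ratio combination analysis
#'
#' Fits the median-effect line to each single drug, computes each
#' combination row's single-drug equivalent doses at the row's observed
#' effect, and emits the combination index, dose-reduction indices and
#' synergy call per row, plus Fa-CI curve points for plotting.
#'
#' @param single1,single2 single-drug tables (columns dose, fa).
#' @param combo combination table (columns dose1, dose2, fa).
#' @param bands additivity band for the synergy call.
#' @param fa_grid fraction-affected grid for the Fa-CI curve (computed at
#'   the combination's dose ratio).
#' @return list of class `combination_analysis`: `fit1`, `fit2`
#'   (median-effect fits), `rows` (dose1, dose2, fa, dx1, dx2, ci, call,
#'   dri1, dri2) and `fa_ci_curve` (fa, ci).
#' @export
analyze_combination <- function(single1, single2, combo,
                                bands = c(0.8, 1.2),
                                fa_grid = seq(0.05, 0.95, by = 0.01)) {
  stopifnot(all(c("dose", "fa") %in% names(single1)),
            all(c("dose", "fa") %in% names(single2)),
            all(c("dose1", "dose2", "fa") %in% names(combo)))
  fit1 <- fit_median_effect(single1$dose, single1$fa)
  fit2 <- fit_median_effect(single2$dose, single2$fa)

  fa <- pmin(pmax(combo$fa, 1e-6), 1 - 1e-6)
  dx1 <- equivalent_dose(fit1, fa)
  dx2 <- equivalent_dose(fit2, fa)
  ci <- combination_index(combo$dose1, combo$dose2, dx1, dx2)
  rows <- data.frame(
    dose1 = combo$dose1, dose2 = combo$dose2, fa = combo$fa,
    dx1 = dx1, dx2 = dx2, ci = ci,
    call = classify_ci(ci, bands),
    dri1 = dose_reduction_index(combo$dose1, dx1),
    dri2 = dose_reduction_index(combo$dose2, dx2),
    stringsAsFactors = FALSE
  )

  # Fa-CI curve at the design's constant ratio: for each effect level the
  # total dose keeping the observed combination potency is interpolated
  # from a median-effect fit of the combination itself
  ratio <- stats::median(combo$dose2 / combo$dose1)
  fit_mix <- fit_median_effect(combo$dose1 + combo$dose2, fa)
  tot <- equivalent_dose(fit_mix, fa_grid)
  d1g <- tot / (1 + ratio); d2g <- tot - d1g
  cig <- combination_index(d1g, d2g,
                           equivalent_dose(fit1, fa_grid),
                           equivalent_dose(fit2, fa_grid))
  structure(list(fit1 = fit1, fit2 = fit2, rows = rows,
                 fa_ci_curve = data.frame(fa = fa_grid, ci = cig)),
            class = "combination_analysis")
}

#' @export
print.combination_analysis <- function(x, ...) {
  cat("Constant-ratio combination analysis\n")
  cat(sprintf("  drug 1: Dm = %.4g, m = %.3f (r = %.3f)\n",
              x$fit1$dm, x$fit1$m, x$fit1$r))
  cat(sprintf("  drug 2: Dm = %.4g, m = %.3f (r = %.3f)\n",
              x$fit2$dm, x$fit2$m, x$fit2$r))
  rows <- x$rows
  rows$ci <- round(rows$ci, 3)
  rows$dri1 <- round(rows$dri1, 3); rows$dri2 <- round(rows$dri2, 3)
  print(rows[, c("dose1", "dose2", "fa", "ci", "call", "dri1", "dri2")],
        row.names = FALSE)
  invisible(x)
}
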