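#' Configuration of the qHTS analysis thresholds
#'
#' All decision thresholds of the screen analysis in one place. Efficacy
#' comparisons follow the screen's wording exactly: activity requires
#' efficacy strictly greater than `eff_active`; the high-efficacy subclass
#' (x.1) requires efficacy greater than or equal to `eff_high`.
#'
#' @param eff_active activity threshold, % (strict >).
#' @param eff_high complete/incomplete subclass split, % (>=).
#' @param class4_eff_min minimum fitted efficacy for any non-inactive call, %.
#' @param r2_poor fits with r2 below this are class 3 ("poorly fit").
#' @param noise_mult,noise_floor single-point activity is a response beyond
#'   `noise_mult` times the robust noise level (MAD-based, floored at
#'   `noise_floor` %) at only the highest tested concentration.
#' @param plateau_tol,plateau_min_points an asymptote counts as present when
#'   at least `plateau_min_points` tested concentrations give model
#'   responses within `plateau_tol` of the plateau (fraction of the fitted
#'   window).
#' @param window_tol minimum control window (raw counts) for normalization.
#' @param triage_efficacy which efficacy feeds the activity triage:
#'   `"fitted"` (the 4PL window, default) or `"observed"` (maximal observed
#'   response), the latter matching a reading of the hit definition as
#'   maximal inhibition rather than fitted efficacy.
#' @export
qhts_config <- function(eff_active = 60, eff_high = 80, class4_eff_min = 30,
                        r2_poor = 0.5, noise_mult = 3, noise_floor = 1,
                        plateau_tol = 0.1, plateau_min_points = 2,
                        window_tol = 1e-6,
                        triage_efficacy = c("fitted", "observed")) {
  stopifnot(eff_active > 0, eff_high > eff_active, class4_eff_min < eff_active,
            r2_poor > 0, r2_poor < 1, plateau_tol > 0)
  list(eff_active = eff_active, eff_high = eff_high,
       class4_eff_min = class4_eff_min, r2_poor = r2_poor,
       noise_mult = noise_mult, noise_floor = noise_floor,
       plateau_tol = plateau_tol, plateau_min_points = plateau_min_points,
       window_tol = window_tol,
       triage_efficacy = match.arg(triage_efficacy))
}

#' Normalize raw plate reads against the plate controls
#'
#' Per-well percent activity relative to the positive-control wells (100%
#' inhibition) and the DMSO-only wells (basal, 0%):
#' `100 * (read - median(dmso)) / (median(pos) - median(dmso))`.
#' Control aggregation uses the median, robust to occasional bad wells.
#'
#' @param raw_plate data.frame with at least `read`; control wells are taken
#'   from its `role` column (values `"dmso"`, `"pos_ctrl"`) unless explicit
#'   well indices are supplied.
#' @param pos_ctrl_wells,dmso_wells optional integer/logical row indices
#'   overriding the `role` column.
#' @param window_tol degenerate-window tolerance on
#'   `|median(pos) - median(dmso)|` in raw counts.
#' @return `raw_plate` with a `normalized` column (% activity).
#' @export
normalize_plate <- function(raw_plate, pos_ctrl_wells = NULL,
                            dmso_wells = NULL, window_tol = 1e-6) {
  stopifnot(is.data.frame(raw_plate), "read" %in% names(raw_plate))
  if (is.null(pos_ctrl_wells) || is.null(dmso_wells)) {
    if (!"role" %in% names(raw_plate))
      stop_input("supply control wells or a 'role' column")
    pos_ctrl_wells <- pos_ctrl_wells %||% which(raw_plate$role == "pos_ctrl")
    dmso_wells <- dmso_wells %||% which(raw_plate$role == "dmso")
  }
  pos <- raw_plate$read[pos_ctrl_wells]
  dmso <- raw_plate$read[dmso_wells]
  if (length(pos) < 2 || length(dmso) < 2)
    stop_input("need at least 2 wells per control group")
  m_pos <- stats::median(pos); m_dmso <- stats::median(dmso)
  if (abs(m_pos - m_dmso) < window_tol)
    stop_input("degenerate control window: |median(pos) - median(dmso)| = ",
               format(abs(m_pos - m_dmso)))
  raw_plate$normalized <- 100 * (raw_plate$read - m_dmso) / (m_pos - m_dmso)
  raw_plate
}

#' Assemble per-compound titration series from normalized plates
#'
#' @param norm_plates plate table with `plate_id`, `row`, `col`,
#'   `normalized` (from [normalize_plate()]).
#' @param map compound map (`compound_id`, `plate_id`, `row`, `col`,
#'   `concentration`) as produced by [gen_plate_reads()].
#' @return data.frame compound_id, concentration (uM, increasing within
#'   compound), response (% activity).
#' @export
build_titrations <- function(norm_plates, map) {
  key <- function(d) paste(d$plate_id, d$row, d$col, sep = "\r")
  idx <- match(key(map), key(norm_plates))
  if (anyNA(idx)) stop_input("compound map refers to wells absent from plates")
  out <- data.frame(compound_id = map$compound_id,
                    concentration = map$concentration,
                    response = norm_plates$normalized[idx],
                    stringsAsFactors = FALSE)
  out[order(out$compound_id, out$concentration), , drop = FALSE]
}

.fpl_resid <- function(par, x, y) {
  # par: bottom, top, log ic50, log hill
  y - .fpl(x, par[1], par[2], exp(par[3]), exp(par[4]))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Model: `y = bottom + (top - bottom) / (1 + (ic50/x)^hill)`. Least squares
#' by Levenberg-Marquardt from a deterministic multi-start grid of
#' log-spaced IC50 seeds (no randomness); the best start by residual sum of
#' squares wins. Optimizer failure is reported through the `converged` flag,
#' never an exception.
#'
#' @param series data.frame/list with `concentration` (> 0) and `response`
#'   (% activity), at least 4 points.
#' @return list of class `curve_fit`: ic50 (uM), hill, top, bottom,
#'   efficacy (|top - bottom| capped at the observed response window), r2,
#'   converged, and `obs_max` (maximal observed response).
#' @export
fit_4pl <- function(series) {
  x <- series$concentration
  y <- series$response
  if (length(x) != length(y)) stop_input("unequal concentration/response lengths")
  if (length(x) < 4) stop_input("need at least 4 titration points")
  if (any(!is.finite(x)) || any(x <= 0))
    stop_input("concentrations must be positive and finite")

  sst <- sum((y - mean(y))^2)
  obs_win <- diff(range(y))
  fail <- list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
               bottom = NA_real_, efficacy = 0, r2 = 0,
               converged = FALSE, obs_max = max(abs(y)))

  ic50_starts <- exp(seq(log(min(x) / 3), log(max(x) * 3), length.out = 6))
  hill_starts <- c(1, 2.5)
  best <- NULL
  for (ic in ic50_starts) {
    for (h in hill_starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = c(min(y), max(y), log(ic), log(h)),
          fn = .fpl_resid, x = x, y = y,
          control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 5000)
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || !all(is.finite(fit$par))) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
  }
  if (is.null(best)) return(structure(fail, class = "curve_fit"))

  p <- best$par
  bottom <- p[1]; top <- p[2]; ic50 <- exp(p[3]); hill <- exp(p[4])
  ssr <- best$deviance
  r2 <- if (sst > 1e-12) max(0, 1 - ssr / sst) else 0
  structure(list(
    ic50 = ic50, hill = hill, top = top, bottom = bottom,
    efficacy = min(abs(top - bottom), obs_win),
    r2 = r2,
    # LM success, or an essentially exact fit on which the optimizer ran out
    # of iterations wandering a flat residual manifold
    converged = best$info %in% 1:4 || ssr <= 1e-8 * max(sst, 1),
    obs_max = max(abs(y))
  ), class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 %.4g uM, hill %.3g, window [%.1f, %.1f], efficacy %.1f%%, r2 %.3f%s\n",
              x$ic50, x$hill, x$bottom, x$top, x$efficacy, x$r2,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Assign an Inglese-style concentration-response curve class
#'
#' Classes: 1.1/1.2 complete curves (both asymptotes) with efficacy >= 80% /
#' < 80%; 2.1/2.2 incomplete curves (one asymptote); 3 activity at only the
#' highest concentration or a poor fit; 4 inactive. Decision order:
#' 4 (insufficient efficacy or no fit), then 3 (single-point activity or
#' r2 below threshold), then asymptote completeness (1.x vs 2.x), then the
#' efficacy subclass split. Total, mutually exclusive, exhaustive.
#'
#' An asymptote is counted as present when the fitted plateau is supported
#' by at least `plateau_min_points` tested concentrations whose model
#' response lies within `plateau_tol` of that plateau (as a fraction of the
#' fitted window).
#'
#' @param fit a `curve_fit` from [fit_4pl()] on the same series.
#' @param series the titration series the fit was produced on.
#' @param config thresholds from [qhts_config()].
#' @return one of `"1.1" "1.2" "2.1" "2.2" "3" "4"`.
#' @export
classify_curve <- function(fit, series, config = qhts_config()) {
  if (!fit$converged || fit$efficacy < config$class4_eff_min) return("4")

  x <- series$concentration
  y <- series$response
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)

  # single-point activity: robust noise from the low-concentration half
  low <- y[seq_len(max(2, floor(n / 2)))]
  rob <- max(config$noise_floor, stats::mad(low))
  active_pts <- which(y - stats::median(low) > config$noise_mult * rob)
  if (length(active_pts) == 1 && active_pts == n) return("3")

  if (fit$r2 < config$r2_poor) return("3")

  f <- .fpl(x, fit$bottom, fit$top, fit$ic50, fit$hill)
  win <- abs(fit$top - fit$bottom)
  n_bottom <- sum(abs(f - fit$bottom) <= config$plateau_tol * win)
  n_top <- sum(abs(f - fit$top) <= config$plateau_tol * win)
  k <- config$plateau_min_points
  both <- n_bottom >= k && n_top >= k
  one <- xor(n_bottom >= k, n_top >= k)
  sub <- if (fit$efficacy >= config$eff_high) ".1" else ".2"
  if (both) paste0("1", sub) else if (one) paste0("2", sub) else "3"
}

#' Triage a compound's activity from its curve class and efficacy
#'
#' Actives are compounds with class 1.1, 1.2, 2.1 or 2.2 curves and efficacy
#' strictly above the activity threshold; class 4 curves are inactive; all
#' other compounds (class 3, and class 1.x/2.x below the efficacy cut) are
#' inconclusive.
#'
#' @param curve_class curve class label.
#' @param efficacy efficacy in % (fitted window or observed maximal
#'   response, per the configured triage source).
#' @param config thresholds from [qhts_config()].
#' @return `"active"`, `"inactive"` or `"inconclusive"` (vectorized).
#' @export
triage_activity <- function(curve_class, efficacy, config = qhts_config()) {
  known <- c("1.1", "1.2", "2.1", "2.2", "3", "4")
  if (!all(curve_class %in% known))
    stop_input("unknown curve class label: ",
               paste(setdiff(unique(curve_class), known), collapse = ", "))
  out <- rep("inconclusive", length(curve_class))
  out[curve_class %in% c("1.1", "1.2", "2.1", "2.2") &
        efficacy > config$eff_active] <- "active"
  out[curve_class == "4"] <- "inactive"
  out
}

#' Analyze a full screen: normalize, fit, classify, triage
#'
#' @param plates raw plate table (plate_id, row, col, read, role).
#' @param map compound map (see [build_titrations()]), optionally with a
#'   `category` column carried into the result.
#' @param config thresholds from [qhts_config()].
#' @return data.frame with one row per compound: fitted parameters,
#'   efficacy, r2, converged, obs_max, curve_class and activity.
#' @export
analyze_screen <- function(plates, map, config = qhts_config()) {
  norm <- do.call(rbind, lapply(split(plates, plates$plate_id),
                                normalize_plate,
                                window_tol = config$window_tol))
  series_all <- build_titrations(norm, map)
  by_cpd <- split(series_all, series_all$compound_id)

  rows <- lapply(by_cpd, function(s) {
    fit <- fit_4pl(s)
    cls <- classify_curve(fit, s, config)
    eff_for_triage <- if (config$triage_efficacy == "observed")
      fit$obs_max else fit$efficacy
    data.frame(compound_id = s$compound_id[1],
               ic50 = fit$ic50, hill = fit$hill,
               top = fit$top, bottom = fit$bottom,
               efficacy = fit$efficacy, obs_max = fit$obs_max,
               r2 = fit$r2, converged = fit$converged,
               curve_class = cls,
               activity = triage_activity(cls, eff_for_triage, config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if ("category" %in% names(map))
    out$category <- map$category[match(out$compound_id, map$compound_id)]
  out
}

.class_rank <- c("1.1" = 1, "1.2" = 2, "2.1" = 3, "2.2" = 4, "3" = 5, "4" = 6)

#' Rank active hits by curve-class confidence and potency
#'
#' Sort key: curve-class confidence (1.1 < 1.2 < 2.1 < 2.2), then ascending
#' IC50 within the class block, ties broken by compound id for determinism.
#' Only active compounds are returned.
#'
#' @param calls screen results (from [analyze_screen()] or equivalent) with
#'   columns compound_id, curve_class, ic50, efficacy, activity, and
#'   optionally name/category.
#' @param top_n number of hits to return; if more than the available
#'   actives, all are returned with a warning.
#' @return ranked hit table.
#' @export
rank_hits <- function(calls, top_n = 50) {
  act <- calls[calls$activity == "active", , drop = FALSE]
  if (nrow(act) == 0) return(act)
  ord <- order(.class_rank[act$curve_class], act$ic50, act$compound_id)
  act <- act[ord, , drop = FALSE]
  if (top_n > nrow(act)) {
    warning("requested ", top_n, " hits but only ", nrow(act),
            " actives available; returning all")
    top_n <- nrow(act)
  }
  out <- act[seq_len(top_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Therapeutic-category enrichment of active compounds
#'
#' Per category: total compounds, actives, and the enrichment ratio
#' `100 * n_active / n_total` (in %), with a flag marking categories above
#' the enrichment threshold (20% by convention).
#'
#' @param calls screen results with compound_id, category and activity.
#' @param flag_threshold enrichment-ratio flag cutoff, %.
#' @return data.frame (category, n_total, n_active, active_fraction,
#'   enrichment_ratio, flagged), sorted by descending ratio.
#' @export
category_enrichment <- function(calls, flag_threshold = 20) {
  stopifnot(all(c("category", "activity") %in% names(calls)))
  calls <- calls[!is.na(calls$category) & nzchar(calls$category), , drop = FALSE]
  tot <- table(calls$category)
  act <- table(calls$category[calls$activity == "active"])
  cats <- names(tot)[tot > 0]
  n_act <- as.integer(act[cats]); n_act[is.na(n_act)] <- 0L
  out <- data.frame(
    category = cats,
    n_total = as.integer(tot[cats]),
    n_active = n_act,
    stringsAsFactors = FALSE
  )
  out$active_fraction <- out$n_active / out$n_total
  out$enrichment_ratio <- 100 * out$active_fraction
  out$flagged <- out$enrichment_ratio > flag_threshold
  out <- out[order(-out$enrichment_ratio, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
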