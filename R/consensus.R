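#' Gate fitted results by R-squared
#'
#' Excludes fits whose `r_squared` falls below the threshold, mirroring the
#' practice of dropping timepoints where no proper interaction-model fit can
#' be found (near-flat early-timepoint monotherapy response). The default
#' threshold is 0.8.
#'
#' @param fits list of fitted objects, each carrying `r_squared` (and
#'   optionally `timepoint_h` / `assay_label` identity used in the log).
#' @param threshold minimum acceptable `r_squared`.
#' @return list with `retained` (the passing fits) and `excluded`
#'   (data.frame log: index, r_squared, timepoint_h, assay_label).
#' @export
gate_by_r2 <- function(fits, threshold = 0.8) {
  r2 <- vapply(fits, function(f) {
    if (is.null(f$r_squared)) NA_real_ else f$r_squared
  }, numeric(1))
  keep <- !is.na(r2) & r2 >= threshold
  get_field <- function(f, nm) {
    v <- f[[nm]]
    if (is.null(v)) NA else v
  }
  excluded <- data.frame(
    index = which(!keep),
    r_squared = r2[!keep],
    timepoint_h = vapply(fits[!keep], get_field, numeric(1), nm = "timepoint_h"),
    assay_label = vapply(fits[!keep], function(f) {
      v <- f$assay_label; if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  )
  if (!any(keep)) {
    warning("all fits fall below the R-squared threshold; retained set is empty")
  }
  list(retained = fits[keep], excluded = excluded)
}

#' Mean and SD across reference models
#'
#' The cross-model summary is the unweighted arithmetic mean (and sample SD,
#' n - 1 denominator) of the per-model mean delta scores.
#'
#' @param deltas numeric vector of per-model mean deltas (or a list of
#'   `delta_scores`, whose `mean_delta` fields are used).
#' @return list with `mean`, `sd`, `n`.
#' @export
aggregate_models <- function(deltas) {
  if (is.list(deltas) && all(vapply(deltas, inherits, logical(1), "delta_scores"))) {
    deltas <- vapply(deltas, function(d) d$mean_delta, numeric(1))
  }
  deltas <- as.numeric(deltas)
  if (length(deltas) == 0) stop("no model-level deltas supplied")
  list(mean = mean(deltas),
       sd = if (length(deltas) > 1) stats::sd(deltas) else 0,
       n = length(deltas))
}

#' Mean and SD over a timepoint window
#'
#' Restricts per-timepoint values to an inclusive window (e.g. 28-80 h,
#' excluding early timepoints with no measurable single-agent efficacy) and
#' returns the unweighted mean and sample SD.
#'
#' @param values numeric vector of per-timepoint summaries.
#' @param timepoints matching timepoints in hours.
#' @param window length-2 inclusive window `c(lo, hi)` in hours.
#' @return list with `mean`, `sd`, `n`, `timepoints_used`.
#' @export
aggregate_timepoints <- function(values, timepoints, window = c(28, 80)) {
  stopifnot(length(values) == length(timepoints), length(window) == 2)
  keep <- timepoints >= window[1] & timepoints <= window[2]
  if (!any(keep)) stop("no timepoints fall inside the window")
  v <- values[keep]
  list(mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0,
       n = length(v),
       timepoints_used = timepoints[keep])
}

new_interaction_call <- function(label, basis, value,
                                 strength = "not_applicable") {
  structure(list(label = label, basis = basis, value = value,
                 strength = strength),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s = %.4g -> %s (%s)\n",
              x$basis, x$value, x$label, x$strength))
  invisible(x)
}

#' Classify a delta score
#'
#' Threshold rule on the mean delta (percentage points beyond the reference
#' expectation): `delta <= -5` antagonism, `-5 < delta < 5` additivity,
#' `delta >= 5` synergism. The 5-point threshold is the typical noise level
#' of large-scale combination screens; boundaries are classified inclusively.
#'
#' @param delta mean delta score (percentage points); finite.
#' @return an `interaction_call` with basis `"delta"`.
#' @export
classify_delta <- function(delta) {
  if (!is.finite(delta)) stop("delta must be finite")
  label <- if (delta <= -5) "antagonism" else if (delta >= 5) "synergism" else "additivity"
  new_interaction_call(label, "delta", delta)
}

#' Classify MuSyC synergy parameters
#'
#' One call per basis: the potency folds `alpha12`/`alpha21` and
#' cooperativity folds `gamma12`/`gamma21` are additive at 1 (> 1 synergism,
#' < 1 antagonism), efficacy `beta` is additive at 0 (> 0 synergism, < 0
#' antagonism). Exact equality never survives a fit, so an additivity
#' tolerance band is applied: `beta_tol` absolute on beta, `fold_tol`
#' relative on the folds. Parameters flagged unstable by [musyc_fit()] are
#' classified but marked `not_applicable`.
#'
#' @param surface a fitted [musyc_surface()].
#' @param beta_tol half-width of the additivity band on beta.
#' @param fold_tol relative half-width of the additivity band on folds
#'   (0.05 = +/- 5%).
#' @return named list of `interaction_call`s
#'   (`alpha12, alpha21, beta, gamma12, gamma21`).
#' @export
classify_musyc <- function(surface, beta_tol = 0.05, fold_tol = 0.05) {
  stopifnot(inherits(surface, "musyc_surface"))
  classify_fold <- function(value, basis) {
    label <- if (value > 1 + fold_tol) "synergism"
             else if (value < 1 - fold_tol) "antagonism"
             else "additivity"
    strength <- if (basis %in% surface$flagged_params) "not_applicable" else "applicable"
    new_interaction_call(label, basis, value, strength)
  }
  beta_label <- if (surface$beta > beta_tol) "synergism"
                else if (surface$beta < -beta_tol) "antagonism"
                else "additivity"
  list(alpha12 = classify_fold(surface$alpha12, "alpha12"),
       alpha21 = classify_fold(surface$alpha21, "alpha21"),
       beta = new_interaction_call(beta_label, "beta", surface$beta,
                                   "applicable"),
       gamma12 = classify_fold(surface$gamma12, "gamma12"),
       gamma21 = classify_fold(surface$gamma21, "gamma21"))
}

#' Consensus strength across reference models
#'
#' Agreement between reference models indicates the degree of interaction:
#' every model synergistic is a strong synergy; some but not all synergistic
#' (the rest additive) is a weak synergy; a mix of synergism and antagonism
#' is discordant; no synergism anywhere returns `"none"`.
#'
#' @param calls list of per-model `interaction_call`s (>= 2).
#' @return one of `"strong"`, `"weak"`, `"discordant"`, `"none"`.
#' @export
consensus_strength <- function(calls) {
  if (length(calls) < 2) stop("need calls from at least two models")
  labels <- vapply(calls, function(x) x$label, character(1))
  n_syn <- sum(labels == "synergism")
  n_ant <- sum(labels == "antagonism")
  if (n_syn > 0 && n_ant > 0) return("discordant")
  if (n_syn == length(labels)) return("strong")
  if (n_syn > 0) return("weak")
  "none"
}
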