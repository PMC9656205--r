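#' Concentration-time profile set from a destructive-sampling design
#'
#' In a destructive (sparse) sampling design each animal contributes one
#' terminal sample at a single timepoint, so no true within-animal profile
#' exists; `n` animals per timepoint give `n` index-paired pseudo-profiles.
#'
#' @param time_h sampling times in hours.
#' @param conc_nM concentrations in nM, a matrix with one row per animal
#'   index and one column per timepoint (or a vector for n = 1).
#' @param analyte analyte name.
#' @param tissue `"plasma"`, `"tumour"` or `"other"`.
#' @param condition `"alone"` or `"combination"`.
#' @param dose_mg_kg administered dose.
#' @return object of class `conc_profile`.
#' @export
conc_profile <- function(time_h, conc_nM, analyte = "analyte",
                         tissue = c("plasma", "tumour", "other"),
                         condition = c("alone", "combination"),
                         dose_mg_kg = NA_real_) {
  tissue <- match.arg(tissue)
  condition <- match.arg(condition)
  if (is.vector(conc_nM)) conc_nM <- matrix(conc_nM, nrow = 1)
  if (ncol(conc_nM) != length(time_h)) {
    stop("`conc_nM` must have one column per timepoint")
  }
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (any(conc_nM < 0)) stop("concentrations must be >= 0")
  structure(
    list(analyte = analyte, matrix_tissue = tissue, condition = condition,
         timepoints = as.numeric(time_h), concentrations = conc_nM,
         dose = dose_mg_kg),
    class = "conc_profile"
  )
}

#' Linear trapezoidal AUC
#'
#' `sum((C_i + C_{i+1}) / 2 * (t_{i+1} - t_i))`. For extravascular (oral)
#' dosing the concentration at dose time is zero, so a leading `(0, 0)` point
#' is prepended whenever the first sample time is after dosing.
#'
#' @param times sampling times in hours, strictly ascending.
#' @param concs concentrations (nM), same length.
#' @param prepend_zero prepend a `(0, 0)` point when `times[1] > 0`.
#' @return AUC in nM x h.
#' @export
auc_linear_trapezoid <- function(times, concs, prepend_zero = TRUE) {
  stopifnot(length(times) == length(concs))
  if (length(times) < 2 && !(prepend_zero && times[1] > 0)) {
    stop("need at least two points to integrate")
  }
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly ascending")
  if (prepend_zero && times[1] > 0) {
    times <- c(0, times)
    concs <- c(0, concs)
  }
  sum((utils::head(concs, -1) + utils::tail(concs, -1)) / 2 * diff(times))
}

#' Non-compartmental analysis of destructive-sampling profiles
#'
#' Forms index-paired pseudo-profiles (the k-th animal at every timepoint
#' joined into one profile — a documented convention, since destructive
#' sampling yields no true profiles), computes AUC(0-last) by the linear
#' trapezoidal rule, Cmax and Tmax (earliest time attaining the maximum) per
#' pseudo-profile, and reports mean +/- sample SD. Concentrations below
#' `lloq` are set to 0 before integration. No extrapolation beyond the last
#' sample is performed.
#'
#' @param profile a [conc_profile()] with >= 2 timepoints.
#' @param lloq lower limit of quantification (nM); values below are zeroed.
#' @return object of class `nca_result`: `auc_0_t`, `cmax`, `tmax` (each
#'   `mean`/`sd`), `n`, plus the per-pseudo-profile table in `$per_profile`.
#' @export
nca_from_pseudoprofiles <- function(profile, lloq = 0) {
  stopifnot(inherits(profile, "conc_profile"))
  tp <- profile$timepoints
  if (length(tp) < 2) stop("need >= 2 timepoints")
  conc <- profile$concentrations
  if (anyNA(conc)) {
    bad <- tp[colSums(is.na(conc)) > 0]
    stop("unequal animal numbers across timepoints (missing values at t = ",
         paste(bad, collapse = ", "), " h)")
  }
  conc[conc < lloq] <- 0
  n <- nrow(conc)
  per <- data.frame(
    animal_index = seq_len(n),
    auc_0_t = apply(conc, 1, function(cc) auc_linear_trapezoid(tp, cc)),
    cmax = apply(conc, 1, max),
    tmax = apply(conc, 1, function(cc) tp[which.max(cc)])
  )
  summarize <- function(x) list(mean = mean(x),
                                sd = if (n > 1) stats::sd(x) else 0)
  structure(
    list(analyte = profile$analyte, tissue = profile$matrix_tissue,
         condition = profile$condition,
         auc_0_t = summarize(per$auc_0_t),
         cmax = summarize(per$cmax),
         tmax = summarize(per$tmax),
         n = n, per_profile = per),
    class = "nca_result"
  )
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %s (%s, %s), n = %d pseudo-profiles\n",
              x$analyte, x$tissue, x$condition, x$n))
  cat(sprintf("  AUC0-t = %.2f +/- %.2f nM*h; Cmax = %.2f +/- %.2f nM; Tmax = %.2f +/- %.2f h\n",
              x$auc_0_t$mean, x$auc_0_t$sd, x$cmax$mean, x$cmax$sd,
              x$tmax$mean, x$tmax$sd))
  invisible(x)
}

#' Combination-vs-monotherapy exposure ratios
#'
#' Ratios of AUC and Cmax means (combination / alone) with a direction flag,
#' quantifying PK interaction at the exposure level.
#'
#' @param combo,mono [nca_from_pseudoprofiles()] results for the same
#'   analyte and tissue.
#' @return data.frame with `metric`, `ratio`, `direction`
#'   (`"increased"`/`"decreased"`/`"unchanged"`).
#' @export
exposure_ratio <- function(combo, mono) {
  stopifnot(inherits(combo, "nca_result"), inherits(mono, "nca_result"))
  if (combo$analyte != mono$analyte || combo$tissue != mono$tissue) {
    stop("exposure_ratio compares the same analyte in the same tissue")
  }
  ratios <- c(auc_0_t = combo$auc_0_t$mean / mono$auc_0_t$mean,
              cmax = combo$cmax$mean / mono$cmax$mean)
  if (any(!is.finite(ratios))) stop("monotherapy metric is zero; ratio undefined")
  data.frame(metric = names(ratios),
             ratio = as.numeric(ratios),
             direction = ifelse(ratios > 1, "increased",
                                ifelse(ratios < 1, "decreased", "unchanged")),
             row.names = NULL)
}

#' Read a sparse-sampling PK CSV
#'
#' Expects columns `analyte, tissue, condition, animal_id, time_h, conc_nM,
#' dose_mg_kg`; returns one [conc_profile()] per (analyte, tissue,
#' condition). Within each group, animals are index-paired per timepoint in
#' `animal_id` order.
#'
#' @param path CSV path.
#' @return named list of `conc_profile`s.
#' @export
read_pk <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "tissue", "condition", "animal_id", "time_h",
            "conc_nM", "dose_mg_kg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("PK file is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  groups <- split(df, interaction(df$analyte, df$tissue, df$condition,
                                  drop = TRUE, lex.order = TRUE))
  out <- lapply(groups, function(g) {
    tp <- sort(unique(g$time_h))
    counts <- table(g$time_h)
    if (length(unique(counts)) != 1) {
      stop("unequal animal numbers across timepoints at t = ",
           paste(names(counts)[counts != max(counts)], collapse = ", "), " h")
    }
    n <- unique(as.integer(counts))
    conc <- matrix(NA_real_, n, length(tp))
    for (j in seq_along(tp)) {
      gg <- g[g$time_h == tp[j], ]
      conc[, j] <- gg$conc_nM[order(gg$animal_id)]
    }
    conc_profile(tp, conc, analyte = g$analyte[1], tissue = g$tissue[1],
                 condition = g$condition[1], dose_mg_kg = g$dose_mg_kg[1])
  })
  out
}
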