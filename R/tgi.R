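#' Tumour volume from calliper width and length
#'
#' Prolate ellipsoid approximation `V = d^2 * D / 2`, with `d` the tumour
#' width (shorter axis, mm) and `D` the length (mm). Swapped inputs (width
#' recorded larger than length, a common transcription slip) are corrected
#' with a warning.
#'
#' @param d width in mm (> 0); vectorized.
#' @param D length in mm (> 0).
#' @return volume in mm^3.
#' @export
tumour_volume <- function(d, D) {
  if (any(d <= 0) || any(D <= 0)) stop("calliper measurements must be > 0")
  swap <- d > D
  if (any(swap)) {
    warning(sprintf("%d measurement(s) with width > length: axes swapped", sum(swap)))
    tmp <- d[swap]; d[swap] <- D[swap]; D[swap] <- tmp
  }
  d^2 * D / 2
}

#' Tumour growth inhibition percentage
#'
#' `TGI (%) = 100 - (T / C * 100)` with `T` the treated and `C` the control
#' tumour size (mm^3). Negative values indicate tumours larger than control.
#'
#' @param T_vol treated tumour size, mm^3 (>= 0); vectorized.
#' @param C_vol control tumour size, mm^3 (> 0).
#' @return TGI in percent.
#' @export
tgi_percent <- function(T_vol, C_vol) {
  if (any(C_vol <= 0)) stop("control volume must be > 0")
  if (any(T_vol < 0)) stop("treated volume must be >= 0")
  100 - (T_vol / C_vol * 100)
}

#' Assemble a xenograft tumour study
#'
#' @param measurements data.frame with columns `group, animal_id, day,
#'   width_mm, length_mm`.
#' @param control_label group label of the vehicle arm.
#' @param schedule optional named character vector of dosing-schedule labels
#'   per group (metadata only).
#' @return object of class `tumour_study` with volumes precomputed.
#' @export
tumour_study <- function(measurements, control_label = "vehicle",
                         schedule = NULL) {
  need <- c("group", "animal_id", "day", "width_mm", "length_mm")
  missing_cols <- setdiff(need, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurements are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!control_label %in% measurements$group) {
    stop("control group '", control_label, "' not present")
  }
  measurements$volume_mm3 <- tumour_volume(measurements$width_mm,
                                           measurements$length_mm)
  structure(list(measurements = measurements,
                 control_label = control_label,
                 schedule = schedule),
            class = "tumour_study")
}

#' Per-day TGI series and maximum TGI for one treated arm
#'
#' For each measurement day shared by the treated and control arms (matched
#' within +/- 1 day for the 2-3x/week calliper schedule), computes per-animal
#' TGI against the control-group MEAN volume, then the group mean +/- SEM
#' (SD / sqrt(n); control uncertainty not propagated). Animals removed
#' mid-study contribute until their last measurement. The headline metric is
#' the maximum of the per-day means, reported with that day's SEM.
#'
#' @param study a [tumour_study()].
#' @param group treated-arm label.
#' @param day_tolerance matching tolerance in days.
#' @return list with `series` (data.frame: day, mean_tgi, sem, n) and
#'   `max_tgi` (list: day, tgi, sem).
#' @export
tgi_series <- function(study, group, day_tolerance = 1) {
  stopifnot(inherits(study, "tumour_study"))
  m <- study$measurements
  ctrl <- m[m$group == study$control_label, ]
  trt <- m[m$group == group, ]
  if (nrow(trt) == 0) stop("no measurements for group '", group, "'")
  ctrl_days <- sort(unique(ctrl$day))
  trt_days <- sort(unique(trt$day))
  rows <- lapply(trt_days, function(day) {
    nearest <- ctrl_days[which.min(abs(ctrl_days - day))]
    if (abs(nearest - day) > day_tolerance) return(NULL)
    c_mean <- mean(ctrl$volume_mm3[ctrl$day == nearest])
    t_vols <- trt$volume_mm3[trt$day == day]
    tgi_i <- tgi_percent(t_vols, c_mean)
    data.frame(day = day,
               mean_tgi = mean(tgi_i),
               sem = if (length(tgi_i) > 1)
                       stats::sd(tgi_i) / sqrt(length(tgi_i)) else 0,
               n = length(tgi_i))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no overlapping measurement days between '",
                              group, "' and control")
  series <- do.call(rbind, rows)
  best <- which.max(series$mean_tgi)
  list(series = series,
       max_tgi = list(day = series$day[best],
                      tgi = series$mean_tgi[best],
                      sem = series$sem[best]))
}

#' Maximum-TGI table across all treated arms
#'
#' @param study a [tumour_study()].
#' @return data.frame with one row per non-control group: `group`, `max_tgi`,
#'   `sem`, `day`.
#' @export
tgi_table <- function(study) {
  groups <- setdiff(unique(study$measurements$group), study$control_label)
  rows <- lapply(groups, function(g) {
    res <- tgi_series(study, g)
    data.frame(group = g, max_tgi = res$max_tgi$tgi,
               sem = res$max_tgi$sem, day = res$max_tgi$day)
  })
  do.call(rbind, rows)
}
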