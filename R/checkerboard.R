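#' Construct a checkerboard response matrix
#'
#' A `response_matrix` holds one replicate/timepoint of a two-drug
#' checkerboard assay: a grid of percentage responses indexed by the row-drug
#' and column-drug concentrations. Concentrations are in nM; a leading 0 dose
#' denotes the vehicle control, so the `(0, 0)` cell, when present, is the
#' untreated well.
#'
#' @param response numeric matrix of percentage responses, rows indexed by
#'   `doses_row`, columns by `doses_col`.
#' @param doses_row,doses_col strictly increasing concentrations (nM). The
#'   first entry may be 0 (vehicle).
#' @param drug_row,drug_col drug names.
#' @param response_scale `"viability"` or `"inhibition"`.
#' @param timepoint_h assay readout time in hours (>= 0).
#' @param replicate_id integer replicate index (>= 1).
#' @param assay_label free-text assay identifier (e.g. `"MTS"`).
#'
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(response, doses_row, doses_col,
                            drug_row = "drug_row", drug_col = "drug_col",
                            response_scale = c("viability", "inhibition"),
                            timepoint_h = 72, replicate_id = 1L,
                            assay_label = "assay") {
  response_scale <- match.arg(response_scale)
  response <- as.matrix(response)
  if (!is.numeric(response)) stop("`response` must be numeric")
  if (nrow(response) != length(doses_row) ||
      ncol(response) != length(doses_col)) {
    stop("`response` must be length(doses_row) x length(doses_col)")
  }
  if (any(doses_row < 0) || any(doses_col < 0)) {
    stop("negative concentrations are not allowed")
  }
  if (is.unsorted(doses_row, strictly = TRUE) ||
      is.unsorted(doses_col, strictly = TRUE)) {
    stop("doses must be strictly increasing")
  }
  if (timepoint_h < 0) stop("`timepoint_h` must be >= 0")
  if (replicate_id < 1) stop("`replicate_id` must be >= 1")
  dimnames(response) <- list(format(doses_row, trim = TRUE),
                             format(doses_col, trim = TRUE))
  structure(
    list(drug_row_name = drug_row, drug_col_name = drug_col,
         doses_row = as.numeric(doses_row), doses_col = as.numeric(doses_col),
         response = response, response_scale = response_scale,
         timepoint_h = as.numeric(timepoint_h),
         replicate_id = as.integer(replicate_id),
         assay_label = assay_label),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %s x %s (%s), %d x %d doses, t = %g h, rep %d [%s]\n",
              x$drug_row_name, x$drug_col_name, x$response_scale,
              length(x$doses_row), length(x$doses_col),
              x$timepoint_h, x$replicate_id, x$assay_label))
  print(round(x$response, 2))
  invisible(x)
}

#' Does the matrix carry both monotherapy edges?
#'
#' Reference-model scoring needs the zero-dose row and column (monotherapy
#' responses of each drug plus the untreated corner).
#'
#' @param mat a [response_matrix()].
#' @return logical.
#' @export
has_monotherapy_edges <- function(mat) {
  mat$doses_row[1] == 0 && mat$doses_col[1] == 0
}

required_checkerboard_cols <- c("block_id", "drug_row", "drug_col",
                                "conc_r", "conc_c", "conc_unit",
                                "response", "response_scale",
                                "time_h", "replicate")

#' Read long-format checkerboard assay data
#'
#' Reads a long-format CSV (SynergyFinder-compatible column semantics) and
#' assembles one [response_matrix()] per `(block, time, replicate)`
#' combination. Doses are sorted ascending; duplicated dose-pair cells within
#' a block/timepoint/replicate are averaged with a warning.
#'
#' @param path CSV file with columns `block_id, drug_row, drug_col, conc_r,
#'   conc_c, conc_unit, response, response_scale, time_h, replicate`.
#' @param conc_multiplier multiplier applied to both concentration columns
#'   (declared unit conversion; concentrations are kept in nM otherwise).
#'
#' @return list of `response_matrix` objects.
#' @export
read_checkerboard <- function(path, conc_multiplier = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_checkerboard_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("checkerboard file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$conc_r < 0) || any(df$conc_c < 0)) {
    stop("negative concentration in checkerboard file")
  }
  df$conc_r <- df$conc_r * conc_multiplier
  df$conc_c <- df$conc_c * conc_multiplier

  keys <- split(df, interaction(df$block_id, df$time_h, df$replicate,
                                drop = TRUE, lex.order = TRUE))
  out <- lapply(keys, function(blk) {
    dr <- sort(unique(blk$conc_r))
    dc <- sort(unique(blk$conc_c))
    # duplicate wells (same dose pair) are technical re-reads: average them
    agg <- stats::aggregate(response ~ conc_r + conc_c, data = blk, FUN = mean)
    if (nrow(agg) < nrow(blk)) {
      warning(sprintf("block %s t=%s rep=%s: %d duplicate dose-pair cells averaged",
                      blk$block_id[1], blk$time_h[1], blk$replicate[1],
                      nrow(blk) - nrow(agg)))
    }
    grid <- matrix(NA_real_, length(dr), length(dc))
    ri <- match(agg$conc_r, dr)
    ci <- match(agg$conc_c, dc)
    grid[cbind(ri, ci)] <- agg$response
    if (anyNA(grid)) {
      miss <- which(is.na(grid), arr.ind = TRUE)
      stop(sprintf("block %s t=%s rep=%s: non-rectangular grid, missing cells: %s",
                   blk$block_id[1], blk$time_h[1], blk$replicate[1],
                   paste(sprintf("(%g, %g)", dr[miss[, 1]], dc[miss[, 2]]),
                         collapse = ", ")))
    }
    scale <- unique(blk$response_scale)
    if (length(scale) != 1 || !scale %in% c("viability", "inhibition")) {
      stop("response_scale must be a single value, 'viability' or 'inhibition'")
    }
    response_matrix(grid, dr, dc,
                    drug_row = blk$drug_row[1], drug_col = blk$drug_col[1],
                    response_scale = scale,
                    timepoint_h = blk$time_h[1],
                    replicate_id = blk$replicate[1],
                    assay_label = as.character(blk$block_id[1]))
  })
  names(out) <- NULL
  out
}

#' Write a list of response matrices back to long-format CSV
#'
#' Inverse of [read_checkerboard()]; the same schema is emitted by the
#' synthetic generator so readers and simulators share one format.
#'
#' @param mats list of [response_matrix()] objects.
#' @param path output CSV path.
#' @export
write_checkerboard <- function(mats, path) {
  if (inherits(mats, "response_matrix")) mats <- list(mats)
  rows <- lapply(mats, function(m) {
    grid <- expand.grid(conc_r = m$doses_row, conc_c = m$doses_col)
    data.frame(block_id = m$assay_label,
               drug_row = m$drug_row_name, drug_col = m$drug_col_name,
               conc_r = grid$conc_r, conc_c = grid$conc_c,
               conc_unit = "nM",
               response = as.vector(m$response),
               response_scale = m$response_scale,
               time_h = m$timepoint_h, replicate = m$replicate_id)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Normalize raw signal to percentage viability or inhibition
#'
#' Viability is `100 * signal / control`; inhibition is `100 - viability`.
#' Inhibition values are clipped to `[0, 100]` for reference-model scoring
#' (the Bliss product form needs fractions), while the unclipped values are
#' retained in the `response_raw` field for curve fitting.
#'
#' @param mat a [response_matrix()] holding raw signal or viability values.
#' @param control the control signal: `"cell00"` uses the `(0, 0)` well,
#'   otherwise supply a positive number.
#' @param to target scale, `"inhibition"` (default, the scale all synergy
#'   computation uses) or `"viability"`.
#'
#' @return a `response_matrix` on the requested scale, carrying unclipped
#'   values in `$response_raw`.
#' @export
normalize_response <- function(mat, control = "cell00",
                               to = c("inhibition", "viability")) {
  to <- match.arg(to)
  stopifnot(inherits(mat, "response_matrix"))
  if (identical(control, "cell00")) {
    if (!has_monotherapy_edges(mat)) {
      stop("control = 'cell00' requires a (0, 0) vehicle cell")
    }
    control <- mat$response[1, 1]
  }
  if (!is.numeric(control) || length(control) != 1 || control <= 0) {
    stop("control signal must be a single positive number")
  }
  if (mat$response_scale == "inhibition") {
    if (to == "inhibition") {
      warning("matrix already on inhibition scale; returning unchanged")
      return(mat)
    }
    stop("cannot renormalize an inhibition-scale matrix back to raw viability")
  }
  viability <- 100 * mat$response / control
  if (to == "viability") {
    out <- mat
    out$response <- viability
    dimnames(out$response) <- dimnames(mat$response)
    out$response_raw <- viability
    return(out)
  }
  inhibition <- 100 - viability
  clipped <- pmin(pmax(inhibition, 0), 100)
  if (any(inhibition != clipped)) {
    warning(sprintf("%d inhibition value(s) outside [0, 100] clipped",
                    sum(inhibition != clipped)))
  }
  out <- mat
  out$response <- clipped
  dimnames(out$response) <- dimnames(mat$response)
  out$response_raw <- inhibition
  out$response_scale <- "inhibition"
  out
}

#' Convert a viability-scale matrix to percent inhibition
#'
#' Assumes viability is already normalized to percent of control (untreated
#' is 100). For raw signals use [normalize_response()].
#'
#' @param mat a [response_matrix()].
#' @param clip clip inhibition to `[0, 100]` (unclipped values are kept in
#'   `$response_raw` regardless).
#' @return inhibition-scale `response_matrix`.
#' @export
as_inhibition <- function(mat, clip = TRUE) {
  stopifnot(inherits(mat, "response_matrix"))
  if (mat$response_scale == "inhibition") return(mat)
  inhibition <- 100 - mat$response
  out <- mat
  out$response_raw <- if (is.null(mat$response_raw)) inhibition
                      else 100 - mat$response_raw
  out$response <- if (clip) pmin(pmax(inhibition, 0), 100) else inhibition
  dimnames(out$response) <- dimnames(mat$response)
  out$response_scale <- "inhibition"
  out
}

# unclipped inhibition values for curve fitting: falls back to the clipped
# grid when no raw field is present (already-clean synthetic input)
raw_inhibition <- function(mat) {
  stopifnot(mat$response_scale == "inhibition")
  if (!is.null(mat$response_raw)) mat$response_raw else mat$response
}
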