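#' Run the full synergy analysis over a set of checkerboard matrices
#'
#' The end-to-end pipeline: converts every matrix to the inhibition scale,
#' scores it under the requested reference models, fits the MuSyC surface,
#' gates MuSyC fits by R-squared, restricts to the timepoint window, and
#' aggregates delta scores per model across replicates/timepoints per assay
#' plus the cross-model mean.
#'
#' @param mats list of [response_matrix()] objects (any scale).
#' @param models reference models to score.
#' @param time_window inclusive analysis window in hours (default 28-80;
#'   matrices outside it are dropped from aggregation). Matrices with a
#'   single static timepoint (e.g. 72 h) fall inside the default window.
#' @param r2_gate minimum MuSyC fit R-squared retained for aggregation.
#' @param fit_musyc set `FALSE` to skip the (slower) surface fits.
#' @param seed provenance seed recorded in the report.
#' @return object of class `synergy_report` with fields `delta_table`
#'   (per matrix x model), `musyc_table` (per matrix), `model_summary`
#'   (per assay x model mean +/- SD), `cross_model` (per assay mean of
#'   model-level means), `musyc_summary`, `excluded` (gate log) and
#'   `provenance`.
#' @export
analyze_checkerboards <- function(mats,
                                  models = c("zip", "loewe", "hsa", "bliss"),
                                  time_window = c(28, 80), r2_gate = 0.8,
                                  fit_musyc = TRUE, seed = NA_integer_) {
  if (inherits(mats, "response_matrix")) mats <- list(mats)
  mats <- lapply(mats, as_inhibition)
  in_window <- vapply(mats, function(m) {
    m$timepoint_h >= time_window[1] && m$timepoint_h <= time_window[2]
  }, logical(1))
  dropped_time <- mats[!in_window]
  mats <- mats[in_window]
  if (length(mats) == 0) stop("no matrices inside the timepoint window")

  delta_rows <- list(); musyc_rows <- list(); musyc_fits <- list()
  for (m in mats) {
    scores <- score_matrix(m, models)
    for (s in scores) {
      delta_rows[[length(delta_rows) + 1]] <- data.frame(
        assay = m$assay_label, timepoint_h = m$timepoint_h,
        replicate = m$replicate_id, model = s$model,
        mean_delta = s$mean_delta, sd_delta = s$sd_delta, n_cells = s$n_cells)
    }
    if (fit_musyc) {
      fit <- musyc_fit(m)
      fit$timepoint_h <- m$timepoint_h
      fit$assay_label <- m$assay_label
      fit$replicate_id <- m$replicate_id
      musyc_fits[[length(musyc_fits) + 1]] <- fit
    }
  }
  delta_table <- do.call(rbind, delta_rows)

  musyc_table <- NULL; excluded <- NULL; musyc_summary <- NULL
  if (fit_musyc && length(musyc_fits) > 0) {
    gated <- gate_by_r2(musyc_fits, threshold = r2_gate)
    excluded <- gated$excluded
    musyc_table <- do.call(rbind, lapply(gated$retained, function(f) {
      data.frame(assay = f$assay_label, timepoint_h = f$timepoint_h,
                 replicate = f$replicate_id,
                 alpha12 = f$alpha12, alpha21 = f$alpha21, beta = f$beta,
                 gamma12 = f$gamma12, gamma21 = f$gamma21,
                 r_squared = f$r_squared,
                 flagged = paste(f$flagged_params, collapse = ";"))
    }))
    if (!is.null(musyc_table) && nrow(musyc_table) > 0) {
      agg_param <- function(param) {
        vals <- lapply(split(musyc_table, musyc_table$assay), function(df) {
          # flagged (boundary-unstable) parameters are excluded from means
          keep <- !grepl(param, df$flagged)
          v <- df[[param]][keep]
          data.frame(assay = df$assay[1], parameter = param,
                     mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                     n = length(v))
        })
        do.call(rbind, vals)
      }
      musyc_summary <- do.call(rbind, lapply(
        c("alpha12", "alpha21", "beta", "gamma12", "gamma21"), agg_param))
      rownames(musyc_summary) <- NULL
    }
  }

  # per assay x model: mean +/- SD of per-matrix deltas
  model_summary <- do.call(rbind, lapply(
    split(delta_table, list(delta_table$assay, delta_table$model), drop = TRUE),
    function(df) data.frame(assay = df$assay[1], model = df$model[1],
                            mean_delta = mean(df$mean_delta),
                            sd_delta = if (nrow(df) > 1) stats::sd(df$mean_delta) else 0,
                            n = nrow(df))))
  rownames(model_summary) <- NULL
  # cross-model mean per assay: unweighted mean of the model-level means
  cross_model <- do.call(rbind, lapply(
    split(model_summary, model_summary$assay),
    function(df) {
      agg <- aggregate_models(df$mean_delta)
      data.frame(assay = df$assay[1], mean_delta = agg$mean,
                 sd_delta = agg$sd, n_models = agg$n)
    }))
  rownames(cross_model) <- NULL

  structure(
    list(delta_table = delta_table, musyc_table = musyc_table,
         model_summary = model_summary, cross_model = cross_model,
         musyc_summary = musyc_summary, excluded = excluded,
         provenance = list(
           seed = seed,
           n_matrices = length(mats),
           n_dropped_outside_window = length(dropped_time),
           time_window = time_window, r2_gate = r2_gate,
           models = toupper(models),
           package = as.character(utils::packageVersion("synercomb")))),
    class = "synergy_report"
  )
}

#' @export
print.synergy_report <- function(x, ...) {
  cat(sprintf("<synergy_report> %d matrices, models: %s\n",
              x$provenance$n_matrices,
              paste(x$provenance$models, collapse = ", ")))
  cat("\nPer-assay model means (delta +/- SD):\n")
  print(x$model_summary, row.names = FALSE)
  cat("\nCross-model means:\n")
  print(x$cross_model, row.names = FALSE)
  if (!is.null(x$musyc_summary)) {
    cat("\nMuSyC parameter means:\n")
    print(x$musyc_summary, row.names = FALSE)
  }
  invisible(x)
}

# replace non-finite numbers by NA (serialized as null) and record where
sanitize_for_json <- function(x, path = "") {
  flags <- character(0)
  walk <- function(x, path) {
    if (is.numeric(x)) {
      bad <- !is.finite(x) & !is.na(x)
      if (any(bad)) {
        flags <<- c(flags, paste0(path, "[", which(bad), "]"))
        x[bad] <- NA_real_
      }
      return(x)
    }
    if (is.data.frame(x) || is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        if (is.null(x[[i]])) next
        nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
        # x[i] <- list(...) keeps a NULL result in place instead of deleting
        # the element and shifting every later index
        x[i] <- list(walk(x[[i]], paste0(path, "/", nm)))
      }
      return(x)
    }
    x
  }
  out <- walk(x, path)
  list(value = out, nonfinite_fields = flags)
}

#' Write an analysis report as JSON
#'
#' Stable field order, full numeric precision; non-finite values are
#' serialized as explicit nulls and listed in the report's
#' `nonfinite_fields` flag so the document round-trips losslessly.
#'
#' @param report a `synergy_report` (or any list-like report).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  s <- sanitize_for_json(unclass(report))
  doc <- s$value
  doc$nonfinite_fields <- s$nonfinite_fields
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", dataframe = "columns")
    TRUE
  }, error = function(e) stop("cannot write report to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a JSON analysis report back
#'
#' @param path path written by [write_report()].
#' @return list mirroring the report structure (tables as data.frames).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
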