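#' Bliss independence expectation
#'
#' Two drugs acting as independent probabilistic events: expected inhibition
#' fraction `y1 + y2 - y1 * y2`.
#'
#' @param y1,y2 inhibition fractions in `[0, 1]` (vectorized).
#' @return expected inhibition fraction.
#' @export
bliss_expected <- function(y1, y2) {
  if (any(y1 < 0 | y1 > 1 | y2 < 0 | y2 > 1)) {
    stop("inhibition fractions must lie in [0, 1]")
  }
  y1 + y2 - y1 * y2
}

#' Highest-single-agent (HSA) expectation
#'
#' The combination is expected to do no better than the stronger monotherapy
#' at its component dose: `max(y1, y2)`.
#'
#' @inheritParams bliss_expected
#' @return expected inhibition fraction.
#' @export
hsa_expected <- function(y1, y2) {
  if (any(y1 < 0 | y1 > 1 | y2 < 0 | y2 > 1)) {
    stop("inhibition fractions must lie in [0, 1]")
  }
  pmax(y1, y2)
}

#' Loewe additivity expectation
#'
#' The response `y` solving the dose-additivity equation
#' `d1 / D1(y) + d2 / D2(y) = 1`, where `Di(y)` is the inverse Hill function
#' of drug i. Solved by bisection on `y` (the left side is strictly
#' decreasing in `y`) to a tolerance of 1e-9. When `y` exceeds one drug's
#' `Emax` that drug's `Di(y)` is infinite and its term vanishes, so a strong
#' partner can carry the expectation past a weaker drug's plateau; a
#' completely inactive drug contributes nothing and the expectation reduces
#' to the active drug's own curve.
#'
#' @param curve1,curve2 inhibition-scale [hill_curve()]s; a curve with
#'   `Emax <= E0` is treated as an inactive drug.
#' @param d1,d2 doses (nM) of drugs 1 and 2.
#' @param tol bisection tolerance on `y`.
#' @return expected inhibition (%). At `d1 = d2 = 0` returns `max(E0)`s; a
#'   root pushed beyond the jointly achievable range returns the boundary
#'   with attribute `boundary = TRUE`.
#' @export
loewe_expected <- function(curve1, curve2, d1, d2, tol = 1e-9) {
  # a curve with no dose-driven inhibition gain (Emax <= E0, as near-flat
  # noisy monotherapy data can fit) is an inactive drug: its dose contributes
  # nothing to the additivity sum
  active1 <- curve1$Emax > curve1$E0
  active2 <- curve2$Emax > curve2$E0
  if (!active1 && !active2) {
    out <- max(curve1$E0, curve2$E0)
    attr(out, "boundary") <- TRUE
    return(out)
  }
  if (!active1) return(hill_predict(curve2, d2))
  if (!active2) return(hill_predict(curve1, d1))
  y_lo <- max(curve1$E0, curve2$E0)
  if (d1 == 0 && d2 == 0) return(y_lo)
  if (d2 == 0) return(hill_predict(curve1, d1))
  if (d1 == 0) return(hill_predict(curve2, d2))
  y_hi <- max(curve1$Emax, curve2$Emax)

  lhs <- function(y) {
    D1 <- hill_inverse(curve1, y)
    D2 <- hill_inverse(curve2, y)
    (if (is.finite(D1)) d1 / D1 else 0) + (if (is.finite(D2)) d2 / D2 else 0)
  }
  eps <- 1e-12 * (y_hi - y_lo)
  lo <- y_lo + eps
  hi <- y_hi - eps
  if (lhs(hi) > 1) {
    out <- y_hi
    attr(out, "boundary") <- TRUE
    return(out)
  }
  if (lhs(lo) < 1) {
    out <- y_lo
    attr(out, "boundary") <- TRUE
    return(out)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (lhs(mid) > 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

new_delta_scores <- function(model, cellwise, flagged = NULL) {
  vals <- cellwise[!is.na(cellwise)]
  structure(
    list(model = model, cellwise_delta = cellwise,
         mean_delta = mean(vals),
         sd_delta = stats::sd(vals),
         n_cells = length(vals),
         flagged = flagged),
    class = "delta_scores"
  )
}

#' @export
print.delta_scores <- function(x, ...) {
  cat(sprintf("<delta_scores> %s: mean delta = %.3f +/- %.3f over %d combination cells\n",
              x$model, x$mean_delta, x$sd_delta, x$n_cells))
  invisible(x)
}

# monotherapy Hill fits from the zero-dose edges of an inhibition matrix;
# ZIP convention pins E0 = 0, Emax = 100
fit_monotherapy_edges <- function(mat, zip = FALSE) {
  if (!has_monotherapy_edges(mat)) {
    stop("matrix must carry monotherapy edges (zero-dose row and column)")
  }
  resp <- raw_inhibition(mat)
  fixed <- if (zip) list(E0 = 0, Emax = 100) else list()
  list(row = fit_hill(mat$doses_row, resp[, 1], fixed = fixed),
       col = fit_hill(mat$doses_col, resp[1, ], fixed = fixed))
}

# fitted monotherapy inhibition (%) clipped to [0, 100] so Bliss/HSA see
# proper fractions
fitted_edge_values <- function(curves, mat) {
  list(row = pmin(pmax(hill_predict(curves$row, mat$doses_row), 0), 100),
       col = pmin(pmax(hill_predict(curves$col, mat$doses_col), 0), 100))
}

combo_cells_mask <- function(mat) {
  outer(mat$doses_row > 0, mat$doses_col > 0, FUN = "&")
}

#' Cell-wise and mean delta scores under a reference model
#'
#' The delta score of a combination cell is the observed inhibition minus the
#' inhibition expected under a non-interaction reference model, in percentage
#' points: a mean delta of 10 means the combination produced on average 10%
#' more response than the reference predicts. Expected responses are built
#' from FITTED monotherapy Hill curves (not raw edge wells) for all models,
#' as the ZIP construction requires; means are taken over combination cells
#' only (both doses > 0).
#'
#' @param mat an inhibition-scale [response_matrix()] with monotherapy edges.
#' @param model `"bliss"`, `"hsa"`, `"loewe"` or `"zip"`.
#' @param curves optional precomputed monotherapy fits (list with `row`,
#'   `col`), as returned by internal edge fitting; supplied by
#'   [score_matrix()] so the four models share one pair of fits.
#' @return a `delta_scores` object: `cellwise_delta` grid (NA on monotherapy
#'   edges), `mean_delta`, `sd_delta`, `n_cells`.
#' @export
delta_matrix <- function(mat, model = c("bliss", "hsa", "loewe", "zip"),
                         curves = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(mat, "response_matrix"))
  if (mat$response_scale != "inhibition") {
    stop("delta scoring expects an inhibition-scale matrix")
  }
  if (model == "zip") return(zip_delta_matrix(mat))
  if (is.null(curves)) curves <- fit_monotherapy_edges(mat)
  fitted <- fitted_edge_values(curves, mat)
  nr <- length(mat$doses_row); nc <- length(mat$doses_col)
  expected <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      expected[i, j] <- switch(model,
        bliss = 100 * bliss_expected(fitted$row[i] / 100, fitted$col[j] / 100),
        hsa = hsa_expected(fitted$row[i] / 100, fitted$col[j] / 100) * 100,
        loewe = as.numeric(loewe_expected(curves$row, curves$col,
                                          mat$doses_row[i], mat$doses_col[j])))
    }
  }
  delta <- mat$response - expected
  delta[!combo_cells_mask(mat)] <- NA_real_
  new_delta_scores(toupper(model), delta)
}

#' ZIP (zero interaction potency) delta scores
#'
#' The ZIP expectation is the Bliss combination of the fitted monotherapy
#' curves under the bounded-response convention (`E0 = 0`, `Emax = 100`). The
#' observed side is smoothed by conditioned Hill fits: along each fixed
#' column dose `d2`, a two-parameter Hill in `d1` with lower asymptote pinned
#' at the fitted monotherapy value `y2(d2)` and upper asymptote 100 (and
#' symmetrically along rows). The cell delta is the average of the two
#' conditioned predictions minus the Bliss expectation; a conditioned fit
#' that fails falls back to the raw Bliss delta for that line and is flagged.
#'
#' @param mat an inhibition-scale [response_matrix()] with monotherapy edges.
#' @return a `delta_scores` object (`model = "ZIP"`), with `flagged` listing
#'   any rows/columns whose conditioned fit failed.
#' @export
zip_delta_matrix <- function(mat) {
  stopifnot(inherits(mat, "response_matrix"))
  if (mat$response_scale != "inhibition") {
    stop("delta scoring expects an inhibition-scale matrix")
  }
  curves <- fit_monotherapy_edges(mat, zip = TRUE)
  resp <- raw_inhibition(mat)
  y1 <- pmin(pmax(hill_predict(curves$row, mat$doses_row), 0), 100)
  y2 <- pmin(pmax(hill_predict(curves$col, mat$doses_col), 0), 100)
  nr <- length(mat$doses_row); nc <- length(mat$doses_col)
  flagged <- character(0)

  # conditioned fit y_c(d | baseline): Hill in d from `baseline` up to 100
  conditioned <- function(doses, responses, baseline) {
    fit <- tryCatch(
      fit_hill(doses, responses, fixed = list(E0 = baseline, Emax = 100)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    pmin(pmax(hill_predict(fit, doses), 0), 100)
  }

  # along d1 at each fixed column dose
  yc_given_col <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc)) {
    pred <- conditioned(mat$doses_row, resp[, j], y2[j])
    if (is.null(pred)) {
      flagged <- c(flagged, sprintf("col %g", mat$doses_col[j]))
    } else {
      yc_given_col[, j] <- pred
    }
  }
  # along d2 at each fixed row dose
  yc_given_row <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    pred <- conditioned(mat$doses_col, resp[i, ], y1[i])
    if (is.null(pred)) {
      flagged <- c(flagged, sprintf("row %g", mat$doses_row[i]))
    } else {
      yc_given_row[i, ] <- pred
    }
  }

  expected <- 100 * outer(y1 / 100, y2 / 100, bliss_expected)
  smoothed <- (yc_given_col + yc_given_row) / 2
  # fallback where a conditioned fit failed: raw observed vs Bliss expectation
  miss <- is.na(smoothed)
  smoothed[miss] <- resp[miss]
  delta <- smoothed - expected
  delta[!combo_cells_mask(mat)] <- NA_real_
  new_delta_scores("ZIP", delta, flagged = unique(flagged))
}

#' Score one checkerboard matrix under several reference models
#'
#' Fits the monotherapy edges once and evaluates every requested model
#' against the same fitted curves, so cross-model comparisons (e.g. the
#' guarantee that HSA deltas dominate Bliss deltas cell-wise) are exact.
#'
#' @param mat an inhibition-scale [response_matrix()] with monotherapy edges.
#' @param models character vector from `c("zip", "loewe", "hsa", "bliss")`.
#' @return named list of `delta_scores`, one per model.
#' @export
score_matrix <- function(mat, models = c("zip", "loewe", "hsa", "bliss")) {
  models <- match.arg(models, c("zip", "loewe", "hsa", "bliss"),
                      several.ok = TRUE)
  curves <- fit_monotherapy_edges(mat)
  out <- lapply(models, function(m) delta_matrix(mat, m, curves = curves))
  names(out) <- toupper(models)
  out
}
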