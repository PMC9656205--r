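#' Four-parameter log-logistic (Hill) curve
#'
#' `E(d) = E0 + (Emax - E0) * d^h / (C^h + d^h)`: `E0` is the response at
#' zero dose, `Emax` the asymptote at infinite dose, `C` the half-maximal
#' concentration (relative EC50, nM) and `h` the Hill slope. On the
#' inhibition scale `100 - Emax` is the resistant plateau: the fraction of
#' cells surviving at arbitrarily high dose.
#'
#' @param E0,Emax responses (%) at zero and infinite dose.
#' @param C half-maximal concentration, nM (> 0).
#' @param h Hill slope (> 0).
#' @param r_squared fit quality (1 for an exact construction).
#' @param converged logical fit-convergence flag.
#' @return object of class `hill_curve`.
#' @export
hill_curve <- function(E0, Emax, C, h, r_squared = 1, converged = TRUE) {
  if (C <= 0) stop("`C` must be > 0")
  if (h <= 0) stop("`h` must be > 0")
  structure(
    list(E0 = E0, Emax = Emax, C = C, h = h,
         r_squared = r_squared, converged = converged,
         resistant_fraction = 100 - Emax),
    class = "hill_curve"
  )
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("<hill_curve> E0 = %.3g, Emax = %.3g, C = %.4g nM, h = %.3g (R^2 = %.4f)\n",
              x$E0, x$Emax, x$C, x$h, x$r_squared))
  invisible(x)
}

#' Predict response from a Hill curve
#'
#' @param curve a [hill_curve()].
#' @param dose concentrations, nM (>= 0; vectorized).
#' @return predicted responses (%); `E0` at dose 0, `Emax` at infinite dose,
#'   `(E0 + Emax) / 2` at `dose = C`.
#' @export
hill_predict <- function(curve, dose) {
  if (any(dose < 0)) stop("dose must be >= 0")
  # d^h / (C^h + d^h) computed on log scale to survive extreme C^h
  f <- ifelse(dose == 0, 0,
              1 / (1 + exp(curve$h * (log(curve$C) - log(pmax(dose, .Machine$double.xmin))))))
  curve$E0 + (curve$Emax - curve$E0) * f
}

hill_sse <- function(par, doses, responses, fixed) {
  cv <- list(E0 = if (is.null(fixed$E0)) par[["E0"]] else fixed$E0,
             Emax = if (is.null(fixed$Emax)) par[["Emax"]] else fixed$Emax,
             C = exp(par[["logC"]]), h = exp(par[["logh"]]))
  class(cv) <- "hill_curve"
  sum((responses - hill_predict(cv, doses))^2)
}

#' Fit a Hill curve by least squares
#'
#' Unweighted nonlinear least squares with `C` and `h` estimated on the log
#' scale. Initialization is deterministic and multi-start: `C` starts at the
#' dose bracketing the half-range response and slopes `h` start at 0.5, 1 and
#' 2; the best converged start wins, so identical inputs always give the same
#' fit.
#'
#' @param doses concentrations, nM (may include 0); at least 4 distinct
#'   values.
#' @param responses observed responses (%), same length.
#' @param fixed optional named list pinning `E0` and/or `Emax` (e.g.
#'   `list(E0 = 0, Emax = 100)` for ZIP-convention fits).
#' @param h_bounds,C_bounds allowed ranges for the slope and the EC50 (the
#'   C default spans the positive dose range widened 1e4-fold each way).
#' @return a [hill_curve()] with `r_squared = 1 - SSres/SStot`; a fit that
#'   fails every start is returned with `converged = FALSE` and
#'   `r_squared = -Inf`.
#' @export
fit_hill <- function(doses, responses, fixed = list(),
                     h_bounds = c(0.05, 20), C_bounds = NULL) {
  stopifnot(length(doses) == length(responses))
  if (any(!is.finite(responses))) stop("responses must be finite")
  if (length(unique(doses)) < 4) stop("need >= 4 distinct doses")
  sstot <- sum((responses - mean(responses))^2)
  if (sstot == 0) stop("degenerate fit: flat response (zero variance)")

  pos <- doses[doses > 0]
  if (is.null(C_bounds)) C_bounds <- c(min(pos) / 1e4, max(pos) * 1e4)

  # deterministic starts: E0/Emax from the dose extremes, C at the dose
  # whose response is nearest the half-range midpoint
  ord <- order(doses)
  d_s <- doses[ord]; r_s <- responses[ord]
  e0_init <- mean(r_s[d_s == min(d_s)])
  emax_init <- mean(r_s[d_s == max(d_s)])
  mid <- (e0_init + emax_init) / 2
  d_pos <- d_s[d_s > 0]
  c_init <- d_pos[which.min(abs(r_s[d_s > 0] - mid))]
  c_starts <- unique(pmin(pmax(c(c_init, exp(mean(log(pos)))), C_bounds[1]), C_bounds[2]))

  free_E0 <- is.null(fixed$E0)
  free_Emax <- is.null(fixed$Emax)
  best <- NULL
  for (h0 in c(0.5, 1, 2)) {
    for (c0 in c_starts) {
      par <- c(logC = log(c0), logh = log(h0))
      lower <- c(logC = log(C_bounds[1]), logh = log(h_bounds[1]))
      upper <- c(logC = log(C_bounds[2]), logh = log(h_bounds[2]))
      if (free_E0) {
        par <- c(par, E0 = e0_init); lower <- c(lower, E0 = -1e3); upper <- c(upper, E0 = 1e3)
      }
      if (free_Emax) {
        par <- c(par, Emax = emax_init); lower <- c(lower, Emax = -1e3); upper <- c(upper, Emax = 1e3)
      }
      fit <- tryCatch(
        stats::nlminb(par, hill_sse, doses = doses, responses = responses,
                      fixed = fixed, lower = lower, upper = upper,
                      control = list(eval.max = 2000, iter.max = 1000,
                                     abs.tol = 0, rel.tol = 1e-14, x.tol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) best <- fit
    }
  }
  if (is.null(best)) {
    cv <- hill_curve(e0_init, emax_init, c_init, 1,
                     r_squared = -Inf, converged = FALSE)
    return(cv)
  }
  p <- best$par
  hill_curve(E0 = if (free_E0) p[["E0"]] else fixed$E0,
             Emax = if (free_Emax) p[["Emax"]] else fixed$Emax,
             C = exp(p[["logC"]]), h = exp(p[["logh"]]),
             r_squared = 1 - best$objective / sstot,
             converged = TRUE)
}

#' Absolute IC50 of an inhibition-scale Hill curve
#'
#' The dose at which predicted inhibition equals 50%, found by inverting the
#' Hill form. Distinct from the relative EC50 (parameter `C`, the
#' half-maximal dose between the curve's own asymptotes): the two coincide
#' only when `E0 = 0` and `Emax = 100`.
#'
#' @param curve a [hill_curve()] on the inhibition scale.
#' @return dose in nM, or `NA_real_` when the curve never crosses 50%
#'   inhibition (`Emax < 50`).
#' @export
absolute_ic50 <- function(curve) {
  f <- (50 - curve$E0) / (curve$Emax - curve$E0)
  if (!is.finite(f) || f <= 0 || f >= 1) return(NA_real_)
  curve$C * (f / (1 - f))^(1 / curve$h)
}

#' Inverse Hill function: dose producing a given response
#'
#' @param curve a [hill_curve()].
#' @param y target response, strictly between `E0` and `Emax`.
#' @return dose in nM; 0 at `y = E0`, `Inf` beyond `Emax`.
#' @export
hill_inverse <- function(curve, y) {
  f <- (y - curve$E0) / (curve$Emax - curve$E0)
  out <- rep(NA_real_, length(f))
  out[f <= 0] <- 0
  out[f >= 1] <- Inf
  ok <- f > 0 & f < 1
  out[ok] <- curve$C * (f[ok] / (1 - f[ok]))^(1 / curve$h)
  out
}

#' Curve-shift table: potency of one drug at each dose of the partner
#'
#' Refits a Hill curve to the responses along one drug at every fixed
#' concentration of the partner drug and tabulates the absolute IC50,
#' exposing potency shifts (a synergistic partner drags the IC50 down with
#' increasing partner dose).
#'
#' @param mat an inhibition-scale [response_matrix()].
#' @param along `"row"` fits along the row drug (one fit per column dose);
#'   `"col"` the converse.
#' @return data.frame with columns `partner_dose`, the four Hill parameters,
#'   `r_squared`, `ic50_abs`, `converged`. Degenerate per-column fits are
#'   flagged (`converged = FALSE`), not fatal.
#' @export
curve_shift <- function(mat, along = c("row", "col")) {
  along <- match.arg(along)
  stopifnot(inherits(mat, "response_matrix"))
  if (mat$response_scale != "inhibition") {
    stop("curve_shift expects an inhibition-scale matrix")
  }
  resp <- raw_inhibition(mat)
  if (along == "col") {
    resp <- t(resp)
    doses <- mat$doses_col; partners <- mat$doses_row
  } else {
    doses <- mat$doses_row; partners <- mat$doses_col
  }
  if (length(doses) < 4) stop("need >= 4 doses along the varying drug")
  rows <- lapply(seq_along(partners), function(j) {
    fit <- tryCatch(fit_hill(doses, resp[, j]),
                    error = function(e) hill_curve(0, 0.1, 1, 1,
                                                   r_squared = -Inf,
                                                   converged = FALSE))
    data.frame(partner_dose = partners[j],
               E0 = fit$E0, Emax = fit$Emax, C = fit$C, h = fit$h,
               r_squared = fit$r_squared,
               ic50_abs = absolute_ic50(fit),
               converged = fit$converged)
  })
  do.call(rbind, rows)
}
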