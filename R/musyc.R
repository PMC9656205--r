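#' MuSyC two-drug dose-response surface
#'
#' The MuSyC model describes a cell population distributed over four states —
#' unaffected (U), affected by drug 1 only (A1), by drug 2 only (A2), and by
#' both (A12) — with mass-action transitions whose rates are Hill-type in the
#' doses. The observed response is the state-weighted mixture of four
#' asymptotic effects `E0, E1, E2, E3` on the viability-fraction scale
#' (`E0 = 1` untreated, `E1`/`E2` the maximal single-agent effects, `E3` the
#' maximal combination effect). Synergy decouples into three fold metrics:
#'
#' * `alpha21` (> 1 synergy) scales the effective dose of drug 1 acting on
#'   cells already affected by drug 2 (transition A2 -> A12); `alpha12`
#'   symmetric.
#' * `gamma21` scales drug 1's Hill slope in that transition; `gamma12`
#'   symmetric.
#' * `beta = (min(E1, E2) - E3) / (E0 - min(E1, E2))` (> 0 synergy), the
#'   fractional increase in maximal effect of the combination over the most
#'   efficacious single agent — derived, not fitted independently.
#'
#' Only rate ratios matter at steady state, so the base rates are fixed at
#' `r1 = r2 = 1` (two unidentifiable parameters removed).
#'
#' @param E0,E1,E2,E3 asymptotic responses (viability fraction scale).
#' @param h1,h2 Hill slopes (> 0).
#' @param C1,C2 half-maximal concentrations, nM (> 0).
#' @param alpha12,alpha21 potency synergy folds (> 0).
#' @param gamma12,gamma21 cooperativity synergy folds (> 0).
#' @param r_squared fit quality (1 for an exact construction).
#' @param converged logical.
#' @param flagged_params names of parameters judged boundary-unstable by the
#'   fit (profile varies > 100-fold); excluded from aggregation by default.
#' @return object of class `musyc_surface` (with derived `beta`).
#' @export
musyc_surface <- function(E0, E1, E2, E3, h1, h2, C1, C2,
                          alpha12 = 1, alpha21 = 1,
                          gamma12 = 1, gamma21 = 1,
                          r_squared = 1, converged = TRUE,
                          flagged_params = character(0)) {
  if (any(c(h1, h2, C1, C2, alpha12, alpha21, gamma12, gamma21) <= 0)) {
    stop("slopes, EC50s and fold parameters must all be > 0")
  }
  structure(
    list(E0 = E0, E1 = E1, E2 = E2, E3 = E3, h1 = h1, h2 = h2,
         C1 = C1, C2 = C2, alpha12 = alpha12, alpha21 = alpha21,
         gamma12 = gamma12, gamma21 = gamma21,
         beta = derive_beta(E0, E1, E2, E3),
         r_squared = r_squared, converged = converged,
         flagged_params = flagged_params),
    class = "musyc_surface"
  )
}

#' @export
print.musyc_surface <- function(x, ...) {
  cat(sprintf("<musyc_surface> E = (%.3g, %.3g, %.3g, %.3g); C = (%.4g, %.4g) nM; h = (%.3g, %.3g)\n",
              x$E0, x$E1, x$E2, x$E3, x$C1, x$C2, x$h1, x$h2))
  cat(sprintf("  alpha12/21 = %.4g / %.4g; beta = %.4g; gamma12/21 = %.4g / %.4g (R^2 = %.4f)\n",
              x$alpha12, x$alpha21, x$beta, x$gamma12, x$gamma21, x$r_squared))
  if (length(x$flagged_params)) {
    cat("  unstable:", paste(x$flagged_params, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Efficacy synergy beta from the four asymptotic effects
#'
#' `beta = (min(E1, E2) - E3) / (E0 - min(E1, E2))`: positive when the
#' combination's maximal effect exceeds the stronger single agent's.
#'
#' @param E0,E1,E2,E3 asymptotic responses on the viability-fraction scale
#'   (lower = more killing).
#' @return beta (dimensionless).
#' @export
derive_beta <- function(E0, E1, E2, E3) {
  best_single <- min(E1, E2)
  denom <- E0 - best_single
  if (denom == 0) stop("derive_beta: E0 equals min(E1, E2) (no single-agent efficacy)")
  (best_single - E3) / denom
}

# transition-rate building blocks; doses/EC50s enter as (x)^h computed in
# log space to survive extreme slopes
pow <- function(x, h) {
  ifelse(x == 0, 0, exp(h * log(x)))
}

# generator matrix of the four-state network, columns/rows (U, A1, A2, A12);
# M[i, j] = rate j -> i for i != j, diagonal = -outflow
musyc_rate_matrix <- function(s, d1, d2) {
  u_a1 <- pow(d1, s$h1);                 a1_u <- pow(s$C1, s$h1)
  u_a2 <- pow(d2, s$h2);                 a2_u <- pow(s$C2, s$h2)
  a2_a12 <- pow(s$alpha21 * d1, s$gamma21 * s$h1)
  a12_a2 <- pow(s$C1, s$gamma21 * s$h1)
  a1_a12 <- pow(s$alpha12 * d2, s$gamma12 * s$h2)
  a12_a1 <- pow(s$C2, s$gamma12 * s$h2)
  M <- matrix(0, 4, 4)
  M[2, 1] <- u_a1;   M[1, 2] <- a1_u
  M[3, 1] <- u_a2;   M[1, 3] <- a2_u
  M[4, 3] <- a2_a12; M[3, 4] <- a12_a2
  M[4, 2] <- a1_a12; M[2, 4] <- a12_a1
  diag(M) <- -colSums(M)
  M
}

#' Steady-state response of the MuSyC four-state network
#'
#' Solves the 4x4 linear balance system (one row replaced by the
#' normalization `U + A1 + A2 + A12 = 1`) and returns the state-weighted
#' response `U*E0 + A1*E1 + A2*E2 + A12*E3`. The solve is done in closed
#' form: eliminating the normalization by Cramer's rule expresses each state
#' occupancy as a sum of four same-sign rate monomials, which are evaluated
#' in log space so extreme slopes or EC50s cannot overflow. At
#' `d1 = d2 = 0` only the untreated state survives and `E0` is returned.
#' With `d2 = 0` the surface collapses exactly to the 1-D Hill curve of
#' drug 1 (and symmetrically).
#'
#' @param surface a [musyc_surface()].
#' @param d1,d2 doses, nM (>= 0; vectorized, recycled to a common length).
#' @param fractions if `TRUE` return the state-occupancy matrix instead of
#'   the response.
#' @return response value(s), or an `n x 4` matrix of fractions (columns
#'   `U, A1, A2, A12`; nonnegative, summing to 1).
#' @export
musyc_steady_state <- function(surface, d1, d2, fractions = FALSE) {
  if (any(d1 < 0) || any(d2 < 0)) stop("doses must be >= 0")
  n <- max(length(d1), length(d2))
  d1 <- rep_len(d1, n); d2 <- rep_len(d2, n)
  s <- surface
  lg <- function(x) ifelse(x == 0, -Inf, log(x))
  # log transition rates: a = U->A1, A = A1->U, b = U->A2, B = A2->U,
  # c = A1->A12, Cc = A12->A1, e = A2->A12, Ee = A12->A2
  la <- s$h1 * lg(d1);                      lA <- s$h1 * log(s$C1)
  lb <- s$h2 * lg(d2);                      lB <- s$h2 * log(s$C2)
  lc <- s$gamma12 * s$h2 * lg(s$alpha12 * d2)
  lCc <- s$gamma12 * s$h2 * log(s$C2)
  le <- s$gamma21 * s$h1 * lg(s$alpha21 * d1)
  lEe <- s$gamma21 * s$h1 * log(s$C1)
  # state occupancies are proportional to sums of 4 rate monomials each
  # (all of one sign), from Cramer's rule on the balance system with U = 1
  lU  <- cbind(lA + lB + lCc, lA + lB + lEe, lA + le + lCc, lc + lB + lEe)
  lA1 <- cbind(la + lB + lCc, la + lB + lEe, la + le + lCc, lb + le + lCc)
  lA2 <- cbind(lA + lb + lCc, lA + lb + lEe, lc + lb + lEe, la + lc + lEe)
  lA12 <- cbind(lA + lb + le, lc + lb + le, la + lB + lc, la + le + lc)
  all_l <- cbind(lU, lA1, lA2, lA12)
  m <- apply(all_l, 1, max)
  w <- exp(all_l - m)
  frac <- cbind(U = rowSums(w[, 1:4, drop = FALSE]),
                A1 = rowSums(w[, 5:8, drop = FALSE]),
                A2 = rowSums(w[, 9:12, drop = FALSE]),
                A12 = rowSums(w[, 13:16, drop = FALSE]))
  frac <- frac / rowSums(frac)
  if (fractions) return(frac)
  as.numeric(frac %*% c(s$E0, s$E1, s$E2, s$E3))
}

musyc_from_theta <- function(theta) {
  musyc_surface(E0 = theta[["E0"]], E1 = theta[["E1"]],
                E2 = theta[["E2"]], E3 = theta[["E3"]],
                h1 = exp(theta[["logh1"]]), h2 = exp(theta[["logh2"]]),
                C1 = exp(theta[["logC1"]]), C2 = exp(theta[["logC2"]]),
                alpha12 = exp(theta[["la12"]]), alpha21 = exp(theta[["la21"]]),
                gamma12 = exp(theta[["lg12"]]), gamma21 = exp(theta[["lg21"]]))
}

#' Fit the MuSyC surface to a checkerboard matrix
#'
#' Nonlinear least squares over the twelve surface parameters, with EC50s,
#' slopes and the four fold parameters estimated in log space (positivity
#' enforced; synergy and antagonism symmetric around log 0). Responses are
#' fitted on the viability-fraction scale (`E0` near 1); an inhibition-scale
#' input is converted internally from its unclipped values. Initialization is
#' deterministic: monotherapy Hill fits seed `E0, E1, E2, h, C`; `E3` starts
#' at the minimum observed response; folds start at 1; a small deterministic
#' multi-start over fold initializations guards against flat directions.
#'
#' Fold parameters whose profile is flat over a 100-fold range (objective
#' change below numerical noise) are reported in `flagged_params`,
#' mirroring the boundary-unstable gamma/alpha estimates such data can
#' produce; flagged values should be excluded from aggregation means.
#'
#' @param mat a [response_matrix()] (viability or inhibition scale) with both
#'   monotherapy edges and >= 4 doses per drug.
#' @param fold_bounds bounds for alpha/gamma folds.
#' @param h_bounds bounds for Hill slopes.
#' @return a fitted [musyc_surface()] with `r_squared` over all cells;
#'   non-convergence returns the best-found surface with
#'   `converged = FALSE`.
#' @export
musyc_fit <- function(mat, fold_bounds = c(1e-5, 1e5), h_bounds = c(0.05, 20)) {
  stopifnot(inherits(mat, "response_matrix"))
  if (!has_monotherapy_edges(mat)) {
    stop("MuSyC fitting requires both monotherapy edges")
  }
  if (length(mat$doses_row) < 5 || length(mat$doses_col) < 5) {
    stop("need >= 4 nonzero doses per drug")
  }
  # viability fraction scale, from unclipped values where available
  v <- if (mat$response_scale == "inhibition") {
    (100 - raw_inhibition(mat)) / 100
  } else {
    mat$response / 100
  }
  if (length(v) < 12) stop("fewer cells than parameters")
  d1 <- mat$doses_row; d2 <- mat$doses_col
  grid <- expand.grid(d1 = d1, d2 = d2)
  obs <- as.vector(v)
  sstot <- sum((obs - mean(obs))^2)
  if (sstot == 0) stop("degenerate fit: flat response surface")

  fit1 <- fit_hill(d1, v[, 1])
  fit2 <- fit_hill(d2, v[1, ])
  e0_init <- mean(c(fit1$E0, fit2$E0))

  objective <- function(theta) {
    s <- tryCatch(musyc_from_theta(theta), error = function(e) NULL)
    if (is.null(s)) return(1e10)
    pred <- musyc_steady_state(s, grid$d1, grid$d2)
    sse <- sum((obs - pred)^2)
    if (!is.finite(sse)) return(1e10)
    sse
  }

  # asymptotes are viability fractions: nonnegative, with headroom above 1
  # for mild stimulation; the lower bound kills a degenerate fit mode where
  # a vanishing fold parameter trades off against a deeply negative E3
  lower <- c(E0 = 0, E1 = 0, E2 = 0, E3 = 0,
             logh1 = log(h_bounds[1]), logh2 = log(h_bounds[1]),
             logC1 = log(min(d1[d1 > 0]) / 1e4), logC2 = log(min(d2[d2 > 0]) / 1e4),
             la12 = log(fold_bounds[1]), la21 = log(fold_bounds[1]),
             lg12 = log(fold_bounds[1]), lg21 = log(fold_bounds[1]))
  upper <- c(E0 = 2, E1 = 2, E2 = 2, E3 = 2,
             logh1 = log(h_bounds[2]), logh2 = log(h_bounds[2]),
             logC1 = log(max(d1) * 1e4), logC2 = log(max(d2) * 1e4),
             la12 = log(fold_bounds[2]), la21 = log(fold_bounds[2]),
             lg12 = log(fold_bounds[2]), lg21 = log(fold_bounds[2]))

  base_start <- c(E0 = e0_init, E1 = fit1$Emax, E2 = fit2$Emax,
                  E3 = min(obs),
                  logh1 = log(fit1$h), logh2 = log(fit2$h),
                  logC1 = log(fit1$C), logC2 = log(fit2$C),
                  la12 = 0, la21 = 0, lg12 = 0, lg21 = 0)
  base_start <- pmin(pmax(base_start, lower), upper)
  starts <- list(base_start)
  for (la in c(log(3), -log(3))) {
    st <- base_start; st[c("la12", "la21")] <- la; starts <- c(starts, list(st))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nlminb(st, objective, lower = lower, upper = upper,
                    control = list(eval.max = 5000, iter.max = 2000,
                                   abs.tol = 0, rel.tol = 1e-15, x.tol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) best <- fit
    if (!is.null(best) && best$objective < 1e-18 * max(sstot, 1)) break
  }
  if (is.null(best)) stop("MuSyC fit failed at every start")

  # polish with a second pass from the optimum
  polish <- tryCatch(
    stats::nlminb(best$par, objective, lower = lower, upper = upper,
                  control = list(eval.max = 5000, iter.max = 2000,
                                 abs.tol = 0, rel.tol = 1e-15, x.tol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$objective <= best$objective) best <- polish

  # profile check on the fold parameters: if moving a fold 10-fold either way
  # barely changes the objective, the parameter is unidentifiable here
  flagged <- character(0)
  noise_floor <- max(best$objective * 1e-4, 1e-12 * sstot)
  fold_names <- c(la12 = "alpha12", la21 = "alpha21",
                  lg12 = "gamma12", lg21 = "gamma21")
  for (nm in names(fold_names)) {
    th_up <- best$par; th_up[nm] <- min(th_up[nm] + log(10), upper[nm])
    th_dn <- best$par; th_dn[nm] <- max(th_dn[nm] - log(10), lower[nm])
    dev <- max(abs(objective(th_up) - best$objective),
               abs(objective(th_dn) - best$objective))
    # flat profile, or an estimate pinned against a fold bound: either way
    # the value is boundary-unstable and should not enter aggregation means
    at_bound <- best$par[nm] <= lower[nm] + 0.01 * log(10) ||
                best$par[nm] >= upper[nm] - 0.01 * log(10)
    if (dev <= noise_floor || at_bound) flagged <- c(flagged, fold_names[[nm]])
  }

  s <- musyc_from_theta(best$par)
  s$r_squared <- 1 - best$objective / sstot
  s$converged <- best$convergence == 0
  s$flagged_params <- flagged
  s
}

#' Predicted checkerboard from a fitted MuSyC surface
#'
#' Evaluates the surface on a dose grid, for residual inspection or export.
#'
#' @param surface a [musyc_surface()].
#' @param doses_row,doses_col dose grids, nM.
#' @param scale `"viability_fraction"` (native) or `"inhibition"` (%).
#' @return numeric matrix indexed by the dose grids.
#' @export
musyc_predict_grid <- function(surface, doses_row, doses_col,
                               scale = c("viability_fraction", "inhibition")) {
  scale <- match.arg(scale)
  grid <- expand.grid(d1 = doses_row, d2 = doses_col)
  pred <- musyc_steady_state(surface, grid$d1, grid$d2)
  m <- matrix(pred, length(doses_row), length(doses_col))
  dimnames(m) <- list(format(doses_row, trim = TRUE),
                      format(doses_col, trim = TRUE))
  if (scale == "inhibition") m <- 100 * (1 - m)
  m
}
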