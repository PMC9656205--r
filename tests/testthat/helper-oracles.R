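# Independent oracles and fixture builders shared across the suite.

# Long-time integration of the four ordinary rate equations dx/dt = M x via
# the matrix exponential, doubling the horizon until the state stops moving.
# Independent of the closed-form steady-state solve in the package.
ode_steady_state <- function(surface, d1, d2) {
  M <- synercomb:::musyc_rate_matrix(surface, d1, d2)
  # one propagator over a short, well-scaled horizon; doubling the horizon by
  # squaring the (column-stochastic) propagator is numerically stable even
  # for stiff rate matrices, unlike exponentiating M * t directly at huge t
  rate <- max(abs(diag(M)), 1e-12)
  E <- as.matrix(Matrix::expm(Matrix::Matrix(M / rate)))
  # fixed squaring schedule: horizon 2^150 / rate covers rate ratios far
  # beyond anything the parameter draws produce, and a premature
  # small-step-difference exit on stiff systems is avoided entirely
  for (i in 1:150) {
    E <- E %*% E
    # the exact propagator conserves mass (columns sum to 1); renormalizing
    # stops float error compounding doubly-exponentially over the squarings
    E <- sweep(E, 2, colSums(E), "/")
  }
  x <- as.numeric(E %*% c(1, 0, 0, 0))
  x / sum(x)
}

ode_steady_response <- function(surface, d1, d2) {
  sum(ode_steady_state(surface, d1, d2) *
        c(surface$E0, surface$E1, surface$E2, surface$E3))
}

# Two-stage grid scan of the Loewe additivity equation: pick the y minimizing
# |d1/D1(y) + d2/D2(y) - 1| on a coarse grid, then rescan finely around it.
# No bisection logic shared with the implementation.
loewe_grid_scan <- function(curve1, curve2, d1, d2, n = 10000) {
  lhs <- function(y) {
    D1 <- hill_inverse(curve1, y)
    D2 <- hill_inverse(curve2, y)
    ifelse(is.finite(D1), d1 / D1, 0) + ifelse(is.finite(D2), d2 / D2, 0)
  }
  lo <- max(curve1$E0, curve2$E0)
  hi <- max(curve1$Emax, curve2$Emax)
  ys <- seq(lo + 1e-9, hi - 1e-9, length.out = n)
  best <- ys[which.min(abs(lhs(ys) - 1))]
  step <- (hi - lo) / n
  ys2 <- seq(max(lo + 1e-12, best - 2 * step),
             min(hi - 1e-12, best + 2 * step), length.out = n)
  ys2[which.min(abs(lhs(ys2) - 1))]
}

# logical mask of combination cells (both doses > 0)
combo_mask <- function(mat) {
  outer(mat$doses_row > 0, mat$doses_col > 0, FUN = "&")
}

# midpoint-rule quadrature of the piecewise-linear interpolant (independent
# of the trapezoid implementation; exact inside segments, O(h^2) at kinks)
quadrature_oracle <- function(times, concs, n = 2^20) {
  f <- stats::approxfun(times, concs)
  h <- (max(times) - min(times)) / n
  mids <- min(times) + (seq_len(n) - 0.5) * h
  sum(f(mids)) * h
}

# random but plausible monotherapy curve on the inhibition scale
random_hill <- function() {
  hill_curve(E0 = 0, Emax = runif(1, 60, 100),
             C = exp(runif(1, -1, 5)), h = runif(1, 0.6, 3))
}

# random MuSyC surface in the moderate regime the assays occupy
random_musyc <- function() {
  musyc_surface(E0 = 1,
                E1 = runif(1, 0, 0.6), E2 = runif(1, 0, 0.6),
                E3 = runif(1, 0, 0.4),
                h1 = runif(1, 0.3, 4), h2 = runif(1, 0.3, 4),
                C1 = exp(runif(1, -2, 6)), C2 = exp(runif(1, -3, 3)),
                alpha12 = exp(runif(1, -2, 2)), alpha21 = exp(runif(1, -2, 2)),
                gamma12 = exp(runif(1, -1, 1)), gamma21 = exp(runif(1, -1, 1)))
}

# inhibition-scale matrix evaluated exactly from a MuSyC surface
matrix_from_surface <- function(surface, grid = "rtglo") {
  g <- dose_grid(grid)
  viab <- musyc_predict_grid(surface, g$doses_row, g$doses_col)
  response_matrix(100 * (1 - viab), g$doses_row, g$doses_col,
                  response_scale = "inhibition")
}

# long-format checkerboard CSV on disk; returns the path
write_checkerboard_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

checkerboard_df <- function(doses_row, doses_col, response,
                            block = "b1", time_h = 72, replicate = 1,
                            scale = "viability") {
  grid <- expand.grid(conc_r = doses_row, conc_c = doses_col)
  data.frame(block_id = block, drug_row = "HDM201", drug_col = "Trametinib",
             conc_r = grid$conc_r, conc_c = grid$conc_c, conc_unit = "nM",
             response = as.vector(response), response_scale = scale,
             time_h = time_h, replicate = replicate)
}
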