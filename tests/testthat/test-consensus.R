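test_that("R-squared gating retains good fits and logs exclusions", {
  fits <- list(list(r_squared = 0.95, timepoint_h = 48, assay_label = "A"),
               list(r_squared = 0.60, timepoint_h = 12, assay_label = "A"))
  g <- gate_by_r2(fits)
  expect_length(g$retained, 1)
  expect_equal(g$retained[[1]]$r_squared, 0.95)
  expect_equal(g$excluded$timepoint_h, 12)
  expect_equal(g$excluded$r_squared, 0.6)

  expect_warning(g2 <- gate_by_r2(list(list(r_squared = 0.1),
                                       list(r_squared = 0.5))), "empty")
  expect_length(g2$retained, 0)
  expect_equal(nrow(g2$excluded), 2)

  # boundary: r_squared exactly at the threshold is retained
  g3 <- gate_by_r2(list(list(r_squared = 0.8)))
  expect_length(g3$retained, 1)
})

test_that("early near-flat timepoints are excluded by the gate", {
  # kinetic series: before the onset delay the surface is flat, so the
  # monotherapy-informed surface fit cannot explain the plate noise
  mats <- generate_matrix(synth_config(61), grid = "rtglo", noise_sd = 2,
                          timepoints_h = c(12, 24, 48, 80), replicates = 1)
  fits <- lapply(mats, function(m) {
    f <- musyc_fit(m)
    f$timepoint_h <- m$timepoint_h
    f
  })
  g <- gate_by_r2(fits, threshold = 0.8)
  retained_t <- vapply(g$retained, function(f) f$timepoint_h, numeric(1))
  expect_true(all(c(12, 24) %in% g$excluded$timepoint_h))
  expect_true(all(c(48, 80) %in% retained_t))
})

test_that("cross-model aggregation is the unweighted mean with sample SD", {
  a <- aggregate_models(c(5.353, 5.111, 12.394, 4.881))
  expect_equal(a$mean, 6.935, tolerance = 5e-4)
  b <- aggregate_models(c(4.858, 7.113, 13.513, 5.540))
  expect_equal(b$mean, 7.756, tolerance = 5e-4)
  expect_equal(b$sd, stats::sd(c(4.858, 7.113, 13.513, 5.540)))

  single <- aggregate_models(42)
  expect_equal(single$mean, 42)
  expect_equal(single$sd, 0)
  expect_error(aggregate_models(numeric(0)), "no model")

  # n identical copies aggregate to the common value
  same <- aggregate_models(rep(3.3, 5))
  expect_equal(same$mean, 3.3)
  expect_equal(same$sd, 0)
})

test_that("timepoint aggregation windows 28-80 h and averages inside it", {
  tps <- c(12, 24, 28, 32, 36, 48, 52, 56, 60, 72, 76, 80)
  vals <- seq_along(tps)
  agg <- aggregate_timepoints(vals, tps, window = c(28, 80))
  expect_equal(agg$timepoints_used, tps[tps >= 28])   # 12 and 24 excluded
  expect_equal(agg$n, 10)
  expect_equal(agg$mean, mean(vals[tps >= 28]))

  same <- aggregate_timepoints(rep(7.7, 4), c(30, 40, 50, 60))
  expect_equal(same$mean, 7.7)
  expect_equal(same$sd, 0)

  two <- aggregate_timepoints(c(2, 8), c(30, 60))
  expect_equal(two$mean, 5)
  expect_error(aggregate_timepoints(1:3, c(1, 2, 3), window = c(28, 80)),
               "window")
})

test_that("delta classification follows the +/-5 point thresholds inclusively", {
  expect_equal(classify_delta(7.482)$label, "synergism")
  expect_equal(classify_delta(0)$label, "additivity")
  expect_equal(classify_delta(-5)$label, "antagonism")   # inclusive boundary
  expect_equal(classify_delta(5)$label, "synergism")     # inclusive boundary
  expect_equal(classify_delta(-4.999)$label, "additivity")
  expect_error(classify_delta(NaN), "finite")

  # monotone: raising delta never moves the label toward antagonism
  rank <- c(antagonism = 1, additivity = 2, synergism = 3)
  labels <- vapply(seq(-10, 10, by = 0.5),
                   function(d) classify_delta(d)$label, character(1))
  expect_true(!is.unsorted(rank[labels]))
})

test_that("MuSyC parameter classification follows the 1/0/1 thresholds", {
  s <- musyc_surface(E0 = 1, E1 = 0.4, E2 = 0.3, E3 = 0.3 - 0.231 * 0.7,
                     h1 = 1, h2 = 1, C1 = 260, C2 = 0.8,
                     alpha12 = 2.162, alpha21 = 1.498,
                     gamma12 = 0.652, gamma21 = 1)
  expect_equal(s$beta, 0.231, tolerance = 1e-12)
  calls <- classify_musyc(s)
  expect_equal(calls$beta$label, "synergism")      # beta = 0.231 > 0
  expect_equal(calls$alpha12$label, "synergism")   # alpha > 1
  expect_equal(calls$gamma12$label, "antagonism")  # gamma = 0.652 < 1
  expect_equal(calls$gamma21$label, "additivity")  # inside tolerance band

  exact <- musyc_surface(E0 = 1, E1 = 0.4, E2 = 0.3, E3 = 0.3,
                         h1 = 1, h2 = 1, C1 = 260, C2 = 0.8)
  calls2 <- classify_musyc(exact)
  expect_equal(calls2$alpha12$label, "additivity") # alpha = 1 exactly
  expect_equal(calls2$beta$label, "additivity")

  # flagged-unstable parameters are called but marked not applicable
  s$flagged_params <- "gamma21"
  expect_equal(classify_musyc(s)$gamma21$strength, "not_applicable")
})

test_that("consensus strength reflects cross-model agreement", {
  syn <- classify_delta(8); add <- classify_delta(1); ant <- classify_delta(-9)
  expect_equal(consensus_strength(list(syn, syn, syn, syn)), "strong")
  expect_equal(consensus_strength(list(add, syn, syn, add)), "weak")
  expect_equal(consensus_strength(list(syn, ant)), "discordant")
  expect_equal(consensus_strength(list(add, add)), "none")
  expect_error(consensus_strength(list(syn)), "two models")
})

test_that("order of aggregation does not change the grand mean", {
  set.seed(13)
  per_model <- matrix(rnorm(4 * 6, 6, 2), 4, 6)  # models x timepoints
  per_model_means <- rowMeans(per_model)
  expect_equal(aggregate_models(per_model_means)$mean, mean(per_model))
})
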