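test_that("Bliss and HSA expectations follow their closed forms", {
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0, 0.37), 0.37)     # identity element
  expect_equal(bliss_expected(1, 0.3), 1)         # absorbing state
  expect_error(bliss_expected(1.2, 0.5), "\\[0, 1\\]")

  expect_equal(hsa_expected(0.3, 0.6), 0.6)
  expect_equal(hsa_expected(0, 0), 0)
  expect_equal(hsa_expected(0.42, 0.42), 0.42)
  expect_error(hsa_expected(-0.1, 0.5), "\\[0, 1\\]")

  # Bliss expectation dominates HSA for all fractions
  set.seed(3)
  y1 <- runif(200); y2 <- runif(200)
  expect_true(all(bliss_expected(y1, y2) >= hsa_expected(y1, y2)))
})

test_that("Loewe expectation satisfies sham additivity and single-agent limits", {
  cv <- hill_curve(0, 100, 1, 1)
  # identical drugs at d1 + d2 = C: exactly half-maximal
  expect_equal(as.numeric(loewe_expected(cv, cv, 0.5, 0.5)), 50,
               tolerance = 1e-8)
  expect_equal(as.numeric(loewe_expected(cv, cv, 2, 0)), hill_predict(cv, 2))
  expect_equal(as.numeric(loewe_expected(cv, cv, 0, 7)), hill_predict(cv, 7))
  expect_equal(as.numeric(loewe_expected(cv, cv, 0, 0)), 0)

  # sham self-combination equals the monotherapy prediction at d1 + d2
  cv2 <- hill_curve(0, 90, 12, 1.7)
  for (d in list(c(1, 3), c(10, 5), c(40, 0.5))) {
    expect_equal(as.numeric(loewe_expected(cv2, cv2, d[1], d[2])),
                 hill_predict(cv2, sum(d)), tolerance = 1e-6)
  }
})

test_that("Loewe bisection agrees with the grid-scan oracle", {
  # asymmetric potency/slope case
  c1 <- hill_curve(0, 100, 1, 1)
  c2 <- hill_curve(0, 100, 10, 2)
  got <- as.numeric(loewe_expected(c1, c2, 0.5, 5))
  expect_equal(got, loewe_grid_scan(c1, c2, 0.5, 5), tolerance = 1e-3)

  set.seed(17)
  for (i in 1:30) {
    a <- random_hill(); b <- random_hill()
    d1 <- exp(runif(1, -2, 4)); d2 <- exp(runif(1, -2, 4))
    y <- loewe_expected(a, b, d1, d2)
    if (is.null(attr(y, "boundary"))) {
      expect_equal(as.numeric(y), loewe_grid_scan(a, b, d1, d2),
                   tolerance = 1e-3)
    }
  }
})

test_that("delta scores vanish on reference-consistent surfaces", {
  m_bliss <- generate_matrix(synth_config(101), grid = "mts",
                             truth = null_truth("bliss"), noise_sd = 0,
                             timepoints_h = 72, replicates = 1)[[1]]
  expect_lt(abs(delta_matrix(m_bliss, "bliss")$mean_delta), 1e-6)

  m_sham <- generate_matrix(synth_config(102), grid = "mts",
                            truth = null_truth("loewe_sham"), noise_sd = 0,
                            timepoints_h = 72, replicates = 1)[[1]]
  expect_lt(abs(delta_matrix(m_sham, "loewe")$mean_delta), 1e-6)

  m_hsa <- generate_matrix(synth_config(103), grid = "mts",
                           truth = null_truth("hsa"), noise_sd = 0,
                           timepoints_h = 72, replicates = 1)[[1]]
  expect_lt(abs(delta_matrix(m_hsa, "hsa")$mean_delta), 1e-6)
})

test_that("ZIP is null on Bliss-consistent surfaces and tracks added synergy", {
  m <- generate_matrix(synth_config(104), grid = "mts",
                       truth = null_truth("bliss"), noise_sd = 0,
                       timepoints_h = 72, replicates = 1)[[1]]
  z0 <- zip_delta_matrix(m)
  expect_lt(abs(z0$mean_delta), 0.1)
  expect_equal(z0$n_cells, 25)              # combination cells only

  # constant +10 points on combination cells lifts mean ZIP delta by ~10;
  # built from gentler full-kill curves so the shifted surface stays below
  # the 100% ceiling
  gentle <- null_truth("bliss", hill_curve(0, 100, 400, 1.2),
                       hill_curve(0, 100, 8, 1))
  mg <- generate_matrix(synth_config(104), grid = "mts", truth = gentle,
                        noise_sd = 0, timepoints_h = 72, replicates = 1)[[1]]
  expect_lt(abs(zip_delta_matrix(mg)$mean_delta), 0.1)
  shifted <- mg
  mask <- combo_mask(mg)
  shifted$response[mask] <- shifted$response[mask] + 10
  shifted$response_raw <- NULL
  expect_equal(zip_delta_matrix(shifted)$mean_delta, 10, tolerance = 0.2)

  # single-drug sham scored by ZIP: near zero but not exactly (documented)
  sham <- generate_matrix(synth_config(105), grid = "mts",
                          truth = null_truth("loewe_sham"), noise_sd = 0,
                          timepoints_h = 72, replicates = 1)[[1]]
  expect_lt(abs(zip_delta_matrix(sham)$mean_delta), 2)
})

test_that("delta grids share translation equivariance and transpose symmetry", {
  s <- default_truth_surface("mts")
  mat <- matrix_from_surface(s, "mts")
  base <- score_matrix(mat)

  # observed = expected surface -> all deltas zero (per model, by construction)
  for (model in c("bliss", "hsa", "loewe")) {
    curves <- synercomb:::fit_monotherapy_edges(mat)
    ds <- delta_matrix(mat, model, curves = curves)
    mat_expected <- mat
    mat_expected$response <- mat$response - ifelse(is.na(ds$cellwise_delta), 0,
                                                   ds$cellwise_delta)
    mat_expected$response_raw <- NULL
    ds0 <- delta_matrix(mat_expected, model)
    expect_lt(max(abs(ds0$cellwise_delta), na.rm = TRUE), 1e-6)
  }

  # +c on every combination cell adds +c to every cell delta (all models)
  shift <- 4
  mask <- combo_mask(mat)
  shifted <- mat
  shifted$response[mask] <- shifted$response[mask] + shift
  shifted$response_raw <- NULL
  sc <- score_matrix(shifted)
  for (model in c("LOEWE", "HSA", "BLISS")) {
    expect_equal(sc[[model]]$cellwise_delta - base[[model]]$cellwise_delta,
                 ifelse(mask, shift, NA), tolerance = 1e-6, ignore_attr = TRUE)
  }

  # transpose symmetry: swapping the two drugs transposes the delta grid
  tmat <- response_matrix(t(mat$response), mat$doses_col, mat$doses_row,
                          response_scale = "inhibition")
  for (model in c("bliss", "hsa", "loewe", "zip")) {
    expect_equal(delta_matrix(tmat, model)$cellwise_delta,
                 t(delta_matrix(mat, model)$cellwise_delta),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("HSA deltas dominate Bliss deltas cell-wise on random matrices", {
  set.seed(33)
  for (i in 1:10) {
    m <- generate_matrix(synth_config(200 + i), grid = "mts",
                         truth = random_musyc(), noise_sd = 3,
                         timepoints_h = 72, replicates = 1,
                         onset_delay_h = 0, t_ref_h = 72)[[1]]
    sc <- score_matrix(m, c("hsa", "bliss"))
    expect_true(all(sc$HSA$cellwise_delta >= sc$BLISS$cellwise_delta - 1e-9,
                    na.rm = TRUE))
  }
})

test_that("Bliss-consistent surfaces read as synergistic under HSA", {
  m <- generate_matrix(synth_config(300), grid = "mts",
                       truth = null_truth("bliss"), noise_sd = 0,
                       timepoints_h = 72, replicates = 1)[[1]]
  expect_gt(delta_matrix(m, "hsa")$mean_delta, 0)
})
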