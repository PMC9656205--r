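test_that("read_checkerboard assembles dose-sorted matrices from long CSV", {
  doses_r <- c(12.5, 25, 50, 100, 200)
  doses_c <- c(0.25, 0.5, 1, 2, 4)
  resp <- matrix(seq(100, 4, length.out = 25), 5, 5)
  df <- checkerboard_df(doses_r, doses_c, resp)
  # shuffle rows: reader must sort doses ascending
  path <- write_checkerboard_csv(df[sample(nrow(df)), ])
  mats <- read_checkerboard(path)
  expect_length(mats, 1)
  m <- mats[[1]]
  expect_s3_class(m, "response_matrix")
  expect_equal(m$doses_row, doses_r)
  expect_equal(m$doses_col, doses_c)
  expect_equal(m$response, resp, ignore_attr = TRUE)
  expect_equal(m$response_scale, "viability")
  expect_equal(m$timepoint_h, 72)
})

test_that("a constant-100 block reads as a constant viability matrix", {
  df <- checkerboard_df(c(1, 2, 4, 8), c(1, 2, 4, 8), matrix(100, 4, 4))
  mats <- read_checkerboard(write_checkerboard_csv(df))
  expect_true(all(mats[[1]]$response == 100))
  expect_equal(mats[[1]]$response_scale, "viability")
})

test_that("kinetic files split into one matrix per timepoint and replicate", {
  g <- dose_grid("rtglo")
  tps <- c(28, 32, 36, 48, 52, 56, 60, 72, 76, 80)
  df <- do.call(rbind, lapply(tps, function(tp) {
    checkerboard_df(g$doses_row, g$doses_col,
                    matrix(50, 8, 8), time_h = tp)
  }))
  mats <- read_checkerboard(write_checkerboard_csv(df))
  expect_length(mats, length(tps))
  expect_setequal(vapply(mats, function(m) m$timepoint_h, numeric(1)), tps)
  # all share one dose grid
  for (m in mats) expect_equal(m$doses_row, g$doses_row)

  df2 <- rbind(checkerboard_df(1:4, 1:4, matrix(1, 4, 4), replicate = 1),
               checkerboard_df(1:4, 1:4, matrix(2, 4, 4), replicate = 2))
  expect_length(read_checkerboard(write_checkerboard_csv(df2)), 2)
})

test_that("reader errors name missing columns, missing cells, bad concentrations", {
  df <- checkerboard_df(1:4, 1:4, matrix(1, 4, 4))
  expect_error(read_checkerboard(write_checkerboard_csv(df[, -4])), "conc_r")
  expect_error(read_checkerboard(write_checkerboard_csv(df[-3, ])),
               "missing cells")
  df_neg <- df; df_neg$conc_c[1] <- -1
  expect_error(read_checkerboard(write_checkerboard_csv(df_neg)), "negative")
})

test_that("duplicate dose-pair cells are averaged with a warning", {
  df <- checkerboard_df(1:4, 1:4, matrix(10, 4, 4))
  dup <- df[1, ]; dup$response <- 30
  expect_warning(mats <- read_checkerboard(write_checkerboard_csv(rbind(df, dup))),
                 "duplicate")
  expect_equal(mats[[1]]$response[1, 1], 20)
})

test_that("write then read is the identity up to float formatting", {
  set.seed(11)
  g <- dose_grid("mts")
  m <- response_matrix(matrix(runif(36, 0, 100), 6, 6),
                       g$doses_row, g$doses_col,
                       response_scale = "inhibition", timepoint_h = 72)
  path <- tempfile(fileext = ".csv")
  write_checkerboard(m, path)
  back <- read_checkerboard(path)[[1]]
  expect_equal(back$response, m$response, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$doses_row, m$doses_row, tolerance = 1e-9)
  expect_equal(back$response_scale, "inhibition")
})

test_that("normalization converts signal to viability and clipped inhibition", {
  m <- response_matrix(matrix(c(100, 80, 60, 50), 2, 2), c(0, 1), c(0, 2))
  n <- normalize_response(m, control = 100)
  expect_equal(n$response[2, 2], 50)         # signal 50 -> inhibition 50
  expect_equal(n$response_scale, "inhibition")
  # inhibition + viability = 100 cell-wise before clipping
  expect_equal(n$response_raw + 100 * m$response / 100, matrix(100, 2, 2),
               ignore_attr = TRUE)

  # control taken from the (0, 0) cell
  n2 <- normalize_response(m, control = "cell00")
  expect_equal(n2$response[1, 1], 0)

  # stimulation above control clips to 0 inhibition with a warning
  m_over <- response_matrix(matrix(c(100, 100, 100, 120), 2, 2), c(0, 1), c(0, 2))
  expect_warning(n3 <- normalize_response(m_over, control = 100), "clipped")
  expect_equal(n3$response[2, 2], 0)
  expect_equal(n3$response_raw[2, 2], -20)   # unclipped value retained

  # signals equal to control -> all-zero inhibition
  flat <- response_matrix(matrix(100, 2, 2), c(0, 1), c(0, 2))
  expect_true(all(normalize_response(flat, control = 100)$response == 0))
})

test_that("normalize is idempotent on an already-normalized matrix", {
  m <- response_matrix(matrix(c(0, 40, 60, 90), 2, 2), c(0, 1), c(0, 2),
                       response_scale = "inhibition")
  expect_warning(again <- normalize_response(m, control = 100), "already")
  expect_identical(again$response, m$response)
  expect_error(normalize_response(m, control = 0), "positive")
})

test_that("constructor enforces grid and dose invariants", {
  expect_error(response_matrix(matrix(1, 2, 3), c(0, 1), c(0, 1)), "length")
  expect_error(response_matrix(matrix(1, 2, 2), c(1, 0), c(0, 1)), "increasing")
  expect_error(response_matrix(matrix(1, 2, 2), c(-1, 0), c(0, 1)), "negative")
  m <- response_matrix(matrix(1, 2, 2), c(0, 1), c(0, 1))
  expect_true(has_monotherapy_edges(m))
  expect_false(has_monotherapy_edges(
    response_matrix(matrix(1, 2, 2), c(1, 2), c(0, 1))))
})
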