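test_that("screen_dataset validates structure and orders wells canonically", {
  w <- data.frame(plate_id = "P1", row = c(1, 0, 1, 0), col = c(1, 1, 0, 0),
                  role = "compound", readout = c(4, 2, 3, 1))
  ds <- screen_dataset(w)
  expect_equal(n_plates(ds), 1L)
  expect_equal(ds$geometry$n_compound, 4L)
  expect_equal(ds$wells$readout, c(1, 2, 3, 4))  # row-major reorder

  expect_error(screen_dataset(w[, -5]), class = "platehit_format_error")
  dup <- rbind(w, w[1, ])
  expect_error(screen_dataset(dup), class = "platehit_integrity_error")
  w2 <- w; w2$readout[2] <- Inf
  expect_error(screen_dataset(w2), class = "platehit_parse_error")
  w3 <- w[-1, ]  # incomplete grid
  expect_error(screen_dataset(w3), class = "platehit_integrity_error")
  w4 <- w; w4$role <- c("compound", "compound", "weird", "neg")
  expect_error(screen_dataset(w4), class = "platehit_format_error")
})

test_that("truth column must cover exactly the compound wells", {
  m <- matrix(1:8, 2, 4)
  w <- plate_df(m, ctrl_cols = c(1, 4))
  w$truth <- ifelse(w$role == "compound", 1L, NA_integer_)
  expect_true(has_truth(screen_dataset(w)))
  w$truth[w$role == "neg"] <- 0L
  expect_error(screen_dataset(w), class = "platehit_integrity_error")
})

test_that("write_plates / read_plates round-trips a simulated screen", {
  spec <- synthetic_spec(n_plates = 10, hit_fraction = 0.1, seed = 7)
  ds <- simulate_screen(spec)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plates(ds, f)
  ds2 <- read_plates(f)
  expect_equal(ds2$wells$plate_id, ds$wells$plate_id)
  expect_equal(ds2$wells$row, ds$wells$row)
  expect_equal(ds2$wells$col, ds$wells$col)
  ## readouts identical to at least 12 printed significant digits
  expect_true(all(abs(ds2$wells$readout - ds$wells$readout) <=
                    1e-12 * pmax(abs(ds$wells$readout), 1)))
  expect_equal(ds2$wells$truth, ds$wells$truth)
})

test_that("read_plates rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,row,col,role", "P1,0,0,compound"), f)
  expect_error(read_plates(f), class = "platehit_format_error")
  writeLines(c("plate_id,row,col,role,readout",
               "P1,0,0,compound,abc", "P1,0,1,compound,1.0"), f)
  expect_error(read_plates(f), class = "platehit_parse_error")
  expect_error(read_plates(file.path(tempdir(), "nope.csv")),
               class = "platehit_format_error")
})

test_that("write_results joins scores, keeps canonical order, round-trips", {
  m <- matrix(rnorm(12), 3, 4)
  ds <- screen_dataset(plate_df(m))
  f <- withr::local_tempfile(fileext = ".csv")

  empty <- data.frame(plate_id = character(), row = integer(),
                      col = integer(), B = numeric())
  write_results(ds, empty, f)
  expect_equal(nrow(utils::read.csv(f)), 0L)

  one <- data.frame(plate_id = "P1", row = 1L, col = 2L, B = 1.5)
  write_results(ds, one, f)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), 1L)
  expect_equal(got$B, 1.5)

  ## full table in scrambled order comes back canonical; readout relation kept
  sc <- compound_wells(ds)[, c("plate_id", "row", "col")]
  sc$Z <- seq_len(nrow(sc))
  sc <- sc[sample(nrow(sc)), ]
  write_results(ds, sc, f)
  back <- read_plates(f)
  expect_equal(back$wells$readout, ds$wells$readout)

  bad <- data.frame(plate_id = "P9", row = 0L, col = 0L, B = 1)
  expect_error(write_results(ds, bad, f), class = "platehit_integrity_error")
})

test_that("standardize_plates gives mean 0 / variance 1 and is idempotent", {
  w <- plate_df(matrix(c(1, 2, 3), 1, 3))
  s <- standardize_plates(screen_dataset(w))
  expect_equal(mean(s$wells$readout), 0)
  expect_equal(var(s$wells$readout), 1)

  expect_error(standardize_plates(screen_dataset(plate_df(matrix(5, 1, 3)))),
               class = "platehit_degenerate_plate_error")

  set.seed(1)
  ds <- screen_dataset(plate_df(matrix(rnorm(80, 5, 3), 8, 10),
                                ctrl_cols = NULL))
  s1 <- standardize_plates(ds)
  x <- s1$wells$readout[s1$wells$role == "compound"]
  expect_lt(abs(mean(x)), 1e-12)
  expect_lt(abs(var(x) - 1), 1e-12)
  s2 <- standardize_plates(s1)
  expect_lt(max(abs(s2$wells$readout - s1$wells$readout)), 1e-10)
})

test_that("controls pass through standardization untouched", {
  m <- matrix(rnorm(24, 10), 4, 6)
  ds <- screen_dataset(plate_df(m, ctrl_cols = c(1, 6)))
  s <- standardize_plates(ds)
  ctl <- ds$wells$role != "compound"
  expect_equal(s$wells$readout[ctl], ds$wells$readout[ctl])
})
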