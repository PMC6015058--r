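test_that("npi matches its defining endpoints and rejects a zero window", {
  expect_equal(npi(100, z_n = 0, z_p = 100), 0)
  expect_equal(npi(0, z_n = 0, z_p = 100), 100)
  expect_equal(npi(25, z_n = 0, z_p = 100), 75)
  expect_equal(npi(c(0, 50, 100), 0, 100), c(100, 50, 0))
  expect_error(npi(1, 2, 2), class = "platehit_control_window_error")
})

test_that("zscore standardizes compound wells under the sample-sd convention", {
  ds <- screen_dataset(plate_df(matrix(c(1, 2, 3), 1, 3)))
  zs <- zscore(ds, "P1")
  expect_equal(zs$values[1, ], c(-1, 0, 1))  # sample sd of 1,2,3 is 1

  set.seed(2)
  m <- matrix(rnorm(48), 4, 12)
  ds2 <- screen_dataset(plate_df(m, ctrl_cols = c(1, 12)))
  zs2 <- zscore(ds2, "P1")
  expect_true(all(is.na(zs2$values[, c(1, 12)])))  # controls not scored
  x <- zs2$values[, 2:11]
  expect_lt(abs(mean(x)), 1e-10)
  expect_lt(abs(var(as.vector(x)) - 1), 1e-10)

  expect_error(zscore(screen_dataset(plate_df(matrix(7, 2, 2))), "P1"),
               class = "platehit_degenerate_plate_error")
})

test_that("median_polish handles degenerate and additive structure", {
  p1 <- median_polish(matrix(3.5, 1, 1))
  expect_equal(p1$overall, 3.5)
  expect_equal(p1$residuals[1, 1], 0)

  re <- c(0, 1, -1, 2); ce <- c(0, -2, 2, 1, -1)
  x <- 10 + outer(re, ce, `+`)
  p <- median_polish(x)
  expect_lt(max(abs(p$residuals)), 1e-12)
  expect_error(median_polish(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "platehit_input_error")
})

test_that("median_polish agrees with a brute-force alternating-median oracle", {
  set.seed(33)
  for (rep in 1:20) {
    x <- matrix(rnorm(80), 8, 10)
    mine <- median_polish(x, tol = 0, max_iter = 200L)
    orc <- oracle_polish(x, sweeps = 200L)
    expect_lt(max(abs(mine$residuals - orc$residuals)), 1e-10)
    expect_lt(abs(mine$overall - orc$overall), 1e-10)
    ## reconstruction identity
    rec <- mine$overall + outer(mine$row_effects, mine$col_effects, `+`) +
      mine$residuals
    expect_lt(max(abs(rec - x)), 1e-12)
    ## residual row/col medians vanish at convergence
    conv <- median_polish(x)
    expect_lt(max(abs(apply(conv$residuals, 1, median))), 1e-8)
    expect_lt(max(abs(apply(conv$residuals, 2, median))), 1e-8)
  }
})

test_that("bscore equals polish residuals over scaled MAD", {
  set.seed(4)
  m <- matrix(rnorm(80, 10, 2), 8, 10)
  ds <- screen_dataset(plate_df(m))
  b <- bscore(ds, "P1")
  pol <- oracle_polish(m, sweeps = 200L)
  mad_o <- 1.4826 * median(abs(pol$residuals - median(pol$residuals)))
  expect_lt(max(abs(b$values - pol$residuals / mad_o)), 1e-8)

  ## sign flip of the plate flips the scores
  bneg <- bscore(screen_dataset(plate_df(-m)), "P1")
  expect_equal(bneg$values, -b$values, tolerance = 1e-10)

  ## purely additive plate: all residuals zero, MAD degenerate
  add <- 5 + outer(1:8, 1:10, `+`)
  expect_error(bscore(screen_dataset(plate_df(add)), "P1"),
               class = "platehit_degenerate_residual_error")
})

test_that("bscore and rscore are shift-invariant and scale-invariant", {
  set.seed(5)
  m <- matrix(rnorm(80, 3, 1), 8, 10)
  ds <- screen_dataset(plate_df(m))
  ds_shift <- screen_dataset(plate_df(m + 17))
  ds_scale <- screen_dataset(plate_df(m * 4.2))
  for (f in list(bscore, rscore)) {
    s0 <- f(ds, "P1")$values
    expect_equal(f(ds_shift, "P1")$values, s0, tolerance = 1e-8)
    expect_equal(f(ds_scale, "P1")$values, s0, tolerance = 1e-8)
  }
})

test_that("rscore flags an exact additive fit and isolates planted outliers", {
  add <- 5 + outer((1:8) / 2, (1:10) / 3, `+`)
  expect_error(rscore(screen_dataset(plate_df(add)), "P1"),
               class = "platehit_degenerate_scale_error")

  set.seed(6)
  m <- add + matrix(rnorm(80, 0, 0.1), 8, 10)
  m[3, 4] <- m[3, 4] + 10
  r <- rscore(screen_dataset(plate_df(m)), "P1")
  expect_equal(which.max(abs(r$values)), which(row(m) == 3 & col(m) == 4))
})

test_that("rscore matches MASS::rlm row+column fits closely", {
  set.seed(7)
  m <- outer(rnorm(8), rnorm(10), `+`) + matrix(rnorm(80, 0, 0.5), 8, 10)
  m[1, 1] <- m[1, 1] + 4
  mine <- rscore(screen_dataset(plate_df(m)), "P1")$values
  y <- as.vector(m)
  ri <- factor(rep(1:8, times = 10)); ci <- factor(rep(1:10, each = 8))
  rf <- MASS::rlm(y ~ ri + ci, psi = MASS::psi.huber, k = 1.345,
                  maxit = 200, contrasts = list(ri = "contr.sum",
                                                ci = "contr.sum"))
  ref <- matrix(rf$residuals / rf$s, 8, 10)
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.999)

  ## B and R estimate the same residual structure on Gaussian plates
  set.seed(8)
  g <- matrix(rnorm(80, 10), 8, 10)
  dsg <- screen_dataset(plate_df(g))
  expect_gt(cor(as.vector(bscore(dsg, "P1")$values),
                as.vector(rscore(dsg, "P1")$values)), 0.9)
})

test_that("score_plates assembles a long table incl. NPI from controls", {
  set.seed(9)
  m <- matrix(rnorm(48, 10), 4, 12)
  m[, 1] <- 0; m[, 12] <- 20   # neg / pos control levels
  ds <- screen_dataset(plate_df(m, ctrl_cols = c(1, 12)))
  tab <- score_plates(ds, methods = c("NPI", "Z", "B", "R"))
  expect_equal(nrow(tab), 40L)
  expect_named(tab, c("plate_id", "row", "col", "NPI", "Z", "B", "R"))
  expect_equal(tab$NPI, npi(tab$Z * sd(m[, 2:11]) + mean(m[, 2:11]), 0, 20),
               tolerance = 1e-8)
})
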