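tiny_dataset <- function(z) {
  nc <- length(z)
  screen_dataset(plate_df(matrix(z, 1, nc)))
}

test_that("stick_weights implements truncated stick-breaking exactly", {
  expect_equal(stick_weights(c(1, 0.3, 0.7)), c(1, 0, 0))
  expect_equal(stick_weights(c(0.5, 0.5, 1)), c(0.5, 0.25, 0.25))
  expect_equal(stick_weights(1), 1)
  set.seed(12)
  for (rep in 1:50) {
    v <- runif(sample(2:30, 1))
    w <- stick_weights(v)
    expect_lt(abs(sum(w) - 1), 1e-15)
    expect_true(all(w >= 0))
  }
  expect_error(stick_weights(c(0.5, 1.2)), class = "platehit_domain_error")
})

test_that("mixture_density is a proper two-channel density", {
  ds <- tiny_dataset(c(0.1, 0.12, 0.3, 0.14))
  pr <- hts_prior(mu00 = 0.1, mu10 = 0.3, a = 3, b = 0.02, H = 3, K = 4)
  st <- init_state(ds, pr, seed = 1)

  grid <- seq(-3, 3, length.out = 20001)
  dens <- mixture_density(grid, st, m = 1)
  expect_true(all(dens > 0))
  integral <- sum(dens) * (grid[2] - grid[1])
  expect_lt(abs(integral - 1), 1e-6)

  ## degenerate single-atom channel: pi = 1 collapses to one normal
  st1 <- st
  st1$pi <- 1
  st1$map[1, , ] <- 1L
  st1$v[1, , ] <- c(1, 1)  # first stick takes all mass in both channels
  d1 <- mixture_density(grid, st1, 1)
  expect_equal(d1, dnorm(grid, st1$mu[1, 2], sqrt(st1$s2[1, 2])),
               tolerance = 1e-12)

  ## mirrored atoms with pi = 0.5 give a symmetric density
  st2 <- st1
  st2$pi <- 0.5
  st2$mu[1, ] <- c(-1, 1)
  st2$s2[1, ] <- 0.25
  d2 <- mixture_density(grid, st2, 1)
  expect_equal(d2, rev(d2), tolerance = 1e-12)
})

test_that("init_state is seed-deterministic and structurally valid", {
  ds <- tiny_dataset(seq(0.05, 0.4, length.out = 10))
  pr <- hts_prior(mu00 = 0.1, mu10 = 0.3, a = 3, b = 0.02, H = 3, K = 4)
  s1 <- init_state(ds, pr, seed = 99)
  s2 <- init_state(ds, pr, seed = 99)
  expect_identical(s1, s2)
  expect_true(any(s1$b == 1L) && any(s1$b == 0L))
  expect_true(all(s1$s2 > 0))
  expect_true(all(s1$v >= 0 & s1$v <= 1))
  expect_error(run_sampler(ds, hts_prior(mu00 = 0.3, mu10 = 0.1,
                                         a = 3, b = 0.02)),
               class = "platehit_validation_error")
})

test_that("gibbs_step preserves state invariants", {
  set.seed(13)
  ds <- gen_model_screen(0.10, seed = 500, n_plates = 3)
  pr <- auto_hyperparameters(ds)
  pr$H <- 4L; pr$K <- 6L
  st <- init_state(ds, pr, seed = 1)
  for (it in 1:30) {
    st <- gibbs_step(st, ds, pr)
    for (m in c(1, 3)) {
      expect_lt(abs(sum(stick_weights(st$v[m, 1, ])) - 1), 1e-12)
      expect_lt(abs(sum(stick_weights(st$v[m, 2, ])) - 1), 1e-12)
    }
    expect_lt(abs(sum(stick_weights(st$u[, 1])) - 1), 1e-12)
    expect_true(all(st$s2 > 0))
    expect_true(st$pi > 0 && st$pi < 1)
    expect_true(all(st$map >= 1L & st$map <= pr$K))
    expect_true(all(st$lab >= 1L & st$lab <= pr$H))
  }
})

test_that("pi concentrates near zero when the data are one inactive atom", {
  set.seed(14)
  z <- rnorm(160, 0.1, 0.02)
  ds <- screen_dataset(plate_df(matrix(z, 8, 20)))
  pr <- hts_prior(mu00 = 0.1, mu10 = 0.3, a = 6, b = 0.002, H = 3, K = 4)
  st <- init_state(ds, pr, seed = 2)
  pis <- numeric(500)
  for (it in 1:500) {
    st <- gibbs_step(st, ds, pr)
    pis[it] <- st$pi
  }
  expect_lt(mean(pis), 0.15)
})

test_that("atom updates follow the Normal-inverse-gamma closed form", {
  ## freeze assignments: single atom per channel (H = 1, K = 1 via direct
  ## state surgery), all wells forced active by a huge channel gap; the
  ## atom draw then has closed-form posterior mean (mu0 + sum z) / (1 + n)
  set.seed(15)
  z <- rnorm(60, 0.5, 0.05)
  ds <- tiny_dataset(z)
  pr <- hts_prior(mu00 = -40, mu10 = 0.5, a = 3, b = 0.02, H = 2, K = 2)
  st <- init_state(ds, pr, seed = 3)
  st$mu[, 1] <- -40; st$mu[, 2] <- 0.5
  st$s2[, ] <- 0.0025
  st$pi <- 0.5
  draws <- replicate(3000, {
    s1 <- gibbs_step(st, ds, pr)   # fresh draw from the same start state
    stopifnot(all(s1$b == 1L))
    k <- unique(s1$map[cbind(1L, 2L, s1$lab)])
    if (length(k) == 1L) s1$mu[k, 2] else NA_real_
  })
  draws <- draws[!is.na(draws)]
  mun <- (pr$mu10 + sum(z)) / (1 + length(z))
  expect_gt(length(draws), 500)
  expect_lt(abs(mean(draws) - mun), 4 * sd(draws) / sqrt(length(draws)) + 1e-6)
})

test_that("run_sampler is reproducible and recovers a separated mixture", {
  ds <- gen_model_screen(0.10, seed = 501, mu0 = 0.10, mu1 = 0.30,
                         sd_atom = 0.02)
  pr <- auto_hyperparameters(ds)
  fit1 <- run_sampler(ds, pr, n_iter = 600, burn_in = 200, thin = 5, seed = 7)
  fit2 <- run_sampler(ds, pr, n_iter = 600, burn_in = 200, thin = 5, seed = 7)
  expect_identical(fit1$hit_prob, fit2$hit_prob)
  expect_identical(fit1$traces, fit2$traces)

  truth <- compound_wells(ds)$truth
  hp <- fit1$hit_prob$hit_prob
  expect_gt(mean(hp[truth == 1]), mean(hp[truth == 0]))
  ## posterior mass matches the generating hit fraction
  expect_lt(abs(mean(hp) - 0.10), 0.05)
  ## hit_prob_draw is exactly the kept-iteration indicator average
  expect_true(all(fit1$hit_prob$hit_prob_draw * fit1$n_kept ==
                    round(fit1$hit_prob$hit_prob_draw * fit1$n_kept)))
  expect_equal(fit1$n_kept, nrow(fit1$traces))
})

test_that("anchored channels stay identified across kept iterations", {
  ds <- gen_model_screen(0.10, seed = 502)
  pr <- auto_hyperparameters(ds)
  fit <- run_sampler(ds, pr, n_iter = 1000, burn_in = 300, thin = 2, seed = 1)
  frac <- mean(fit$traces$chan_mean1 > fit$traces$chan_mean0)
  expect_gte(frac, 0.95)
})

test_that("posterior mean of pi covers the truth on model-generated data", {
  for (pi_true in c(0.01, 0.05, 0.10)) {
    for (s in 1:3) {
      ds <- gen_model_screen(pi_true, seed = 600 + 10 * s)
      pr <- auto_hyperparameters(ds)
      pr$H <- 2L; pr$K <- 2L
      fit <- run_sampler(ds, pr, n_iter = 1200, burn_in = 400, thin = 2,
                         seed = s)
      expect_lt(abs(mean(fit$traces$pi) - pi_true), 0.03)
    }
  }
})

test_that("sweep conditionals pass a Geweke-style joint-consistency check", {
  ## marginal-conditional vs successive-conditional moments must agree on
  ## a tiny instance (1 plate, 20 wells, H = K = 2)
  ds <- tiny_dataset(rep(0.2, 20))
  pr <- hts_prior(mu00 = 0.1, mu10 = 0.3, a = 3, b = 0.02, H = 2, K = 2)
  set.seed(42)
  R <- 3000
  mc <- t(replicate(R, {
    st <- platehit:::prior_state(ds, pr)
    c(st$pi, mean(st$mu[, 1]), mean(st$mu[, 2]))
  }))
  st <- platehit:::prior_state(ds, pr)
  dsi <- regenerate_readouts(st, ds)
  sc <- matrix(NA_real_, R, 3)
  for (t in 1:R) {
    st <- gibbs_step(st, dsi, pr)
    dsi <- regenerate_readouts(st, dsi)
    sc[t, ] <- c(st$pi, mean(st$mu[, 1]), mean(st$mu[, 2]))
  }
  ## prior: pi ~ Beta(1,1) (mean .5, sd .2887); atom means centered at the
  ## anchors. Tolerances are ~4 sigma Monte Carlo bounds allowing for the
  ## successive-conditional chain autocorrelation (ESS of order R/10).
  expect_lt(abs(mean(sc[, 1]) - mean(mc[, 1])), 0.08)
  expect_lt(abs(sd(sc[, 1]) - sd(mc[, 1])), 0.045)
  expect_lt(abs(mean(sc[, 2]) - mean(mc[, 2])), 0.03)
  expect_lt(abs(mean(sc[, 3]) - mean(mc[, 3])), 0.03)
})
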