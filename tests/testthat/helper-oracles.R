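# Independent brute-force oracles, deliberately coded with plain loops and
# no shared helpers with the package implementation.

## Tukey polish by explicit alternating median sweeps, fixed sweep count
oracle_polish <- function(x, sweeps = 200L) {
  nr <- nrow(x); nc <- ncol(x)
  r <- x; oa <- 0; re <- rep(0, nr); ce <- rep(0, nc)
  for (s in seq_len(sweeps)) {
    for (i in seq_len(nr)) {
      m <- median(r[i, ]); re[i] <- re[i] + m; r[i, ] <- r[i, ] - m
    }
    d <- median(ce); oa <- oa + d; ce <- ce - d
    for (j in seq_len(nc)) {
      m <- median(r[, j]); ce[j] <- ce[j] + m; r[, j] <- r[, j] - m
    }
    d <- median(re); oa <- oa + d; re <- re - d
  }
  list(overall = oa, row_effects = re, col_effects = ce, residuals = r)
}

## FDR estimator as an explicit loop
oracle_fdr <- function(p, r) {
  num <- 0; den <- 0
  for (i in seq_along(p)) {
    if (p[i] > r) {
      num <- num + (1 - p[i])
      den <- den + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

## AUC via the Mann-Whitney U statistic (ranks with ties averaged)
oracle_auc_u <- function(scores, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  rk <- rank(scores)
  (sum(rk[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## data generated from the mixture model itself: two well-separated atoms
## per channel, fixed component sd, Bernoulli(pi) activity
gen_model_screen <- function(pi_true, seed, n_plates = 10L, n_rows = 8L,
                             n_cols = 10L,
                             mu0 = c(0.10, 0.14), mu1 = c(0.30, 0.35),
                             sd_atom = 0.02) {
  set.seed(seed)
  n <- n_plates * n_rows * n_cols
  b <- rbinom(n, 1, pi_true)
  z <- ifelse(b == 1L,
              rnorm(n, mu1[sample.int(length(mu1), n, replace = TRUE)], sd_atom),
              rnorm(n, mu0[sample.int(length(mu0), n, replace = TRUE)], sd_atom))
  w <- data.frame(plate_id = rep(sprintf("P%03d", seq_len(n_plates)),
                                 each = n_rows * n_cols),
                  row = rep(rep(seq_len(n_rows) - 1L, each = n_cols), n_plates),
                  col = rep(seq_len(n_cols) - 1L, n_plates * n_rows),
                  role = "compound", readout = z, truth = b)
  screen_dataset(w)
}

## small complete plate with optional control columns, from a value matrix
plate_df <- function(m, plate_id = "P1", ctrl_cols = integer()) {
  nr <- nrow(m); nc <- ncol(m)
  role <- matrix("compound", nr, nc)
  if (length(ctrl_cols) >= 1L) role[, ctrl_cols[1L]] <- "neg"
  if (length(ctrl_cols) >= 2L) role[, ctrl_cols[2L]] <- "pos"
  data.frame(plate_id = plate_id,
             row = rep(seq_len(nr) - 1L, times = nc),
             col = rep(seq_len(nc) - 1L, each = nr),
             role = as.vector(role), readout = as.vector(m))
}
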