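#' ROC curve and AUC
#'
#' Builds the empirical ROC curve of a real-valued predictor against
#' binary truth (higher score = more active) and computes the area under
#' it by the trapezoid rule. Tied scores collapse into a single cutoff
#' (a diagonal segment), making the AUC identical to the Mann-Whitney
#' U-statistic with 1/2 credit per tie.
#'
#' @param scores numeric predictor, one per well.
#' @param truth 0/1 labels, both classes present.
#' @return an object of class `roc_curve`: `points` (data.frame `fpr`,
#'   `tpr` from (0,0) to (1,1)) and `auc`.
#' @export
roc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth) || anyNA(scores) || anyNA(truth)) {
    ph_stop("scores and truth must be complete and of equal length",
            "platehit_input_error")
  }
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    ph_stop("ROC undefined: both classes must be present",
            "platehit_undefined_roc_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t1 <- truth[ord]
  ## collapse ties: cumulative counts at the last index of each tie group
  nn <- length(s)
  last <- c(which(diff(s) != 0), nn)
  tp <- cumsum(t1)[last]
  fp <- cumsum(1L - t1)[last]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Best-threshold AUC of a binarized score
#'
#' For each cutoff `t` on a grid, evaluates the AUC of the binary
#' predictor `1(score > t)`, which equals `(TPR(t) + TNR(t)) / 2` (the ROC
#' of a binary predictor is piecewise linear through a single interior
#' point). Mimics hit calling with a hard score threshold, the way B- and
#' R-scores are used in practice; the returned maximizer is the "best
#' achievable threshold" benchmark.
#'
#' @inheritParams roc
#' @param n_grid number of evenly spaced cutoffs spanning the observed
#'   score range.
#' @return an object of class `threshold_sweep`: `thresholds`,
#'   `auc_at_threshold`, `best_threshold`, `best_auc`.
#' @export
binary_sweep_auc <- function(scores, truth, n_grid = 101L) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    ph_stop("sweep undefined: both classes must be present",
            "platehit_undefined_roc_error")
  }
  grid <- seq(min(scores), max(scores), length.out = n_grid)
  auc_t <- vapply(grid, function(t) {
    called <- scores > t
    tpr <- sum(called & truth == 1L) / n1
    tnr <- sum(!called & truth == 0L) / n0
    (tpr + tnr) / 2
  }, numeric(1))
  best <- which.max(auc_t)
  structure(list(thresholds = grid, auc_at_threshold = auc_t,
                 best_threshold = grid[best], best_auc = auc_t[best]),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d cutoffs; best AUC %.4f at threshold %.6g\n",
              length(x$thresholds), x$best_auc, x$best_threshold))
  invisible(x)
}

#' Sensitivity of the fit to the atom-anchor separation
#'
#' Re-runs the sampler over a grid of values of the prior anchor
#' difference `mu10 - mu00` (holding `mu00` and everything else fixed) and
#' reports the resulting AUC of the posterior hit probabilities against
#' the dataset truth. Used to verify that hit ranking is flat in the
#' anchors over a wide range.
#'
#' @param dataset a [screen_dataset()] with truth labels.
#' @param prior the base [hts_prior()] (fully specified).
#' @param deltas numeric vector of `mu10 - mu00` values (> 0).
#' @param seed seed passed to every run.
#' @param ... further arguments to [run_sampler()] (`n_iter`, `burn_in`,
#'   `thin`).
#' @return data.frame with columns `delta` and `auc`.
#' @export
sensitivity_sweep <- function(dataset, prior, deltas, seed = 1L, ...) {
  if (!has_truth(dataset)) {
    ph_stop("sensitivity sweep needs truth labels", "platehit_input_error")
  }
  if (any(deltas <= 0)) {
    ph_stop("anchor differences must be positive (mu10 > mu00)",
            "platehit_validation_error")
  }
  truth <- compound_wells(dataset)$truth
  auc <- vapply(deltas, function(d) {
    pr <- prior
    pr$mu10 <- pr$mu00 + d
    fit <- run_sampler(dataset, pr, seed = seed, ...)
    roc(fit$hit_prob$hit_prob, truth)$auc
  }, numeric(1))
  data.frame(delta = deltas, auc = auc)
}

#' MCMC trace diagnostics
#'
#' Per traced scalar: lag autocorrelations (up to lag 50), the trace mean,
#' and the effective sample size `n / (1 + 2 * sum(acf))` with the sum
#' truncated at the first non-positive autocorrelation. Constant traces
#' are flagged (their ACF is undefined beyond lag 0).
#'
#' @param traces data.frame of per-iteration scalars (>= 10 rows), e.g.
#'   the `traces` element of [run_sampler()] output.
#' @param max_lag largest autocorrelation lag.
#' @return list with `summary` (data.frame: `variable`, `mean`, `sd`,
#'   `ess`, `lag1_acf`, `constant`) and `acf` (matrix, lags x variables).
#' @export
mcmc_diagnostics <- function(traces, max_lag = 50L) {
  traces <- as.data.frame(traces)
  n <- nrow(traces)
  if (n < 10L) {
    ph_stop("need at least 10 kept samples for diagnostics",
            "platehit_input_error")
  }
  max_lag <- min(max_lag, n - 1L)
  acfs <- matrix(NA_real_, max_lag, ncol(traces),
                 dimnames = list(seq_len(max_lag), names(traces)))
  sm <- lapply(names(traces), function(v) {
    x <- traces[[v]]
    if (sd(x) == 0) {
      return(data.frame(variable = v, mean = mean(x), sd = 0, ess = NA_real_,
                        lag1_acf = NA_real_, constant = TRUE))
    }
    rho <- drop(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1L]
    acfs[, v] <<- rho
    pos <- which(rho <= 0)
    keep <- if (length(pos)) head(rho, pos[1L] - 1L) else rho
    ess <- n / (1 + 2 * sum(keep))
    data.frame(variable = v, mean = mean(x), sd = sd(x), ess = ess,
               lag1_acf = rho[1L], constant = FALSE)
  })
  list(summary = do.call(rbind, sm), acf = acfs)
}
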