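#' Normalized percent inhibition (NPI)
#'
#' Scales a raw readout between the positive- and negative-control levels:
#' `(z_p - z) / (z_p - z_n) * 100`. A reading at the positive control maps
#' to 0% and at the negative control to 100%.
#'
#' @param z compound readout(s).
#' @param z_n negative-control readout.
#' @param z_p positive-control readout.
#' @return percent inhibition, same length as `z`.
#' @examples
#' npi(25, z_n = 0, z_p = 100)  # 75
#' @export
npi <- function(z, z_n, z_p) {
  if (any(z_p == z_n)) {
    ph_stop("positive and negative control levels coincide (z_p == z_n)",
            "platehit_control_window_error")
  }
  (z_p - z) / (z_p - z_n) * 100
}

new_score_matrix <- function(plate_id, method, values) {
  structure(list(plate_id = plate_id, method = method, values = values),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> plate %s, method %s, %dx%d\n",
              x$plate_id, x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-plate Z-score
#'
#' Standardizes each compound well by the mean and sample standard
#' deviation of all compound wells on the same plate. Control wells are
#' not scored (NA in the output matrix).
#'
#' @param dataset a [screen_dataset()].
#' @param plate_id which plate.
#' @return a `score_matrix` (`method = "Z"`) aligned to the plate geometry.
#' @export
zscore <- function(dataset, plate_id) {
  vals <- plate_matrix(dataset, plate_id, "readout")
  roles <- plate_matrix(dataset, plate_id, "role")
  cw <- roles == "compound"
  x <- vals[cw]
  if (length(x) < 2L) {
    ph_stop(sprintf("plate %s: need >= 2 compound wells", plate_id),
            "platehit_degenerate_plate_error")
  }
  s <- sd(x)
  if (s == 0) {
    ph_stop(sprintf("plate %s has zero compound-well standard deviation",
                    plate_id),
            "platehit_degenerate_plate_error")
  }
  out <- matrix(NA_real_, nrow(vals), ncol(vals))
  out[cw] <- (x - mean(x)) / s
  new_score_matrix(plate_id, "Z", out)
}

#' Tukey median polish
#'
#' Decomposes a complete two-way table into an overall effect, row
#' effects, column effects and residuals by alternating subtraction of
#' row and column medians. Iteration stops when the total absolute
#' adjustment of one full sweep falls below `tol` times the scale of the
#' input (mean absolute value), or after `max_iter` sweeps. The identity
#' `overall + row_effects[i] + col_effects[j] + residuals[i, j] == x[i, j]`
#' holds to floating-point accuracy throughout.
#'
#' @param x numeric matrix, all entries finite.
#' @param tol relative convergence tolerance on the per-sweep adjustment.
#' @param max_iter maximum number of full sweeps.
#' @return list of class `polish_decomposition`: `overall`, `row_effects`,
#'   `col_effects`, `residuals`, `iterations`, `converged`.
#' @export
median_polish <- function(x, tol = 1e-10, max_iter = 100L) {
  if (!is.matrix(x) || !is.numeric(x)) {
    ph_stop("median_polish needs a numeric matrix", "platehit_input_error")
  }
  if (any(!is.finite(x))) {
    ph_stop("median_polish: non-finite entries", "platehit_input_error")
  }
  r <- x
  overall <- 0
  re <- numeric(nrow(x))
  ce <- numeric(ncol(x))
  scale <- mean(abs(x))
  if (scale == 0) scale <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    adj <- 0
    rm_ <- apply(r, 1L, median)
    re <- re + rm_
    r <- r - rm_                      # recycles down columns: r[i,j] - rm_[i]
    adj <- adj + sum(abs(rm_))
    d <- median(ce)
    overall <- overall + d
    ce <- ce - d
    adj <- adj + abs(d)
    cm_ <- apply(r, 2L, median)
    ce <- ce + cm_
    r <- sweep(r, 2L, cm_)
    adj <- adj + sum(abs(cm_))
    d <- median(re)
    overall <- overall + d
    re <- re - d
    adj <- adj + abs(d)
    if (adj < tol * scale) {
      converged <- TRUE
      break
    }
  }
  structure(list(overall = overall, row_effects = re, col_effects = ce,
                 residuals = r, iterations = iter, converged = converged),
            class = "polish_decomposition")
}

## scaled MAD used by the B-score denominator
mad_scaled <- function(x) 1.4826 * median(abs(x - median(x)))

#' Per-plate B-score
#'
#' Strips control wells, median-polishes the complete compound sub-grid to
#' remove additive row/column plate effects, and scales the residuals by
#' their median absolute deviation (with the 1.4826 Gaussian-consistency
#' constant): `B = r / MAD(r)`.
#'
#' @inheritParams zscore
#' @param tol,max_iter passed to [median_polish()].
#' @return a `score_matrix` (`method = "B"`); controls are NA.
#' @export
bscore <- function(dataset, plate_id, tol = 1e-10, max_iter = 100L) {
  sub <- compound_submatrix(dataset, plate_id)
  pol <- median_polish(sub, tol = tol, max_iter = max_iter)
  s <- mad_scaled(pol$residuals)
  if (s == 0) {
    ph_stop(sprintf("plate %s: all polish residuals identical (MAD = 0)",
                    plate_id),
            "platehit_degenerate_residual_error")
  }
  scores_to_plate(dataset, plate_id, sub, pol$residuals / s, "B")
}

## place a compound sub-grid of scores back into full plate geometry
scores_to_plate <- function(dataset, plate_id, sub, scores, method) {
  g <- dataset$geometry[dataset$geometry$plate_id == plate_id, ]
  out <- matrix(NA_real_, g$n_rows, g$n_cols)
  rows <- as.integer(rownames(sub))
  cols <- as.integer(colnames(sub))
  out[rows + 1L, cols + 1L] <- scores
  new_score_matrix(plate_id, method, out)
}

## IRLS fit of z_ij = mu + row_i + col_j with Huber weights and
## sum-to-zero constraints; scale = 1.4826 * median(|residual|),
## re-estimated each iteration (rlm convention).
huber_rowcol_fit <- function(m, k = 1.345, max_iter = 200L, tol = 1e-4) {
  nr <- nrow(m)
  nc <- ncol(m)
  y <- as.vector(m)
  ri <- factor(rep(seq_len(nr), times = nc))
  ci <- factor(rep(seq_len(nc), each = nr))
  X <- stats::model.matrix(~ ri + ci,
                           contrasts.arg = list(ri = "contr.sum", ci = "contr.sum"))
  fit <- stats::lm.fit(X, y)
  coef_old <- fit$coefficients
  res <- fit$residuals
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- 1.4826 * median(abs(res))
    if (s == 0) {
      ph_stop("robust fit is exact (zero residual scale)",
              "platehit_degenerate_scale_error", residuals = res)
    }
    u <- res / s
    w <- ifelse(abs(u) <= k, 1, k / abs(u))
    fit <- lm.wfit(X, y, w)
    res_new <- drop(y - X %*% fit$coefficients)
    ## rlm-style criterion: relative change of the residual vector
    delta <- sqrt(sum((res_new - res)^2) / max(1e-20, sum(res^2)))
    coef_old <- fit$coefficients
    res <- res_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    ph_stop(sprintf("Huber IRLS did not converge in %d iterations", max_iter),
            "platehit_convergence_error",
            last_coefficients = coef_old, last_residuals = res)
  }
  s <- 1.4826 * median(abs(res))
  if (s == 0) {
    ph_stop("robust fit is exact (zero residual scale)",
            "platehit_degenerate_scale_error", residuals = res)
  }
  list(residuals = matrix(res, nr, nc), scale = s)
}

#' Per-plate R-score
#'
#' Like the B-score, but row/column plate effects are estimated by a
#' robust linear model: iteratively reweighted least squares with Huber
#' weights (default tuning constant 1.345, 95% Gaussian efficiency) and
#' sum-to-zero row/column constraints, the scale being the MAD of the
#' residuals re-estimated each iteration. `R = residual / scale`.
#' Convergence is declared when the relative change of the residual
#' vector drops below `tol` (the `rlm` convention; with the scale
#' re-estimated each iteration the coefficients approach their fixed
#' point only geometrically, so much tighter tolerances are unreachable
#' in reasonable iteration counts).
#'
#' @inheritParams zscore
#' @param tuning Huber tuning constant.
#' @param max_iter maximum IRLS iterations.
#' @param tol relative residual-change tolerance.
#' @return a `score_matrix` (`method = "R"`); controls are NA.
#' @export
rscore <- function(dataset, plate_id, tuning = 1.345, max_iter = 200L,
                   tol = 1e-4) {
  sub <- compound_submatrix(dataset, plate_id)
  if (nrow(sub) + ncol(sub) - 1L >= length(sub)) {
    ph_stop(sprintf("plate %s: too few compound wells for a row+column fit",
                    plate_id),
            "platehit_input_error")
  }
  fit <- huber_rowcol_fit(sub, k = tuning, max_iter = max_iter, tol = tol)
  scores_to_plate(dataset, plate_id, sub, fit$residuals / fit$scale, "R")
}

#' Score every plate of a dataset
#'
#' Convenience wrapper computing Z, B and R scores (and NPI when both
#' control types are present on a plate, using the plate-mean control
#' levels) for every plate, returned as one long score table keyed by
#' `(plate_id, row, col)` — the format consumed by [write_results()].
#'
#' @param dataset a [screen_dataset()].
#' @param methods subset of `c("NPI", "Z", "B", "R")`.
#' @return data.frame with key columns plus one column per method
#'   (compound wells only).
#' @export
score_plates <- function(dataset, methods = c("Z", "B", "R")) {
  methods <- match.arg(methods, c("NPI", "Z", "B", "R"), several.ok = TRUE)
  out <- lapply(plate_ids(dataset), function(p) {
    sub <- dataset$wells[dataset$wells$plate_id == p &
                           dataset$wells$role == "compound", ]
    tab <- sub[, c("plate_id", "row", "col")]
    for (mth in methods) {
      if (mth == "NPI") {
        ctl <- dataset$wells[dataset$wells$plate_id == p, ]
        zn <- mean(ctl$readout[ctl$role == "neg"])
        zp <- mean(ctl$readout[ctl$role == "pos"])
        if (!is.finite(zn) || !is.finite(zp)) {
          ph_stop(sprintf("plate %s: NPI needs both control types", p),
                  "platehit_control_window_error")
        }
        tab$NPI <- npi(sub$readout, zn, zp)
      } else {
        sm <- switch(mth,
                     Z = zscore(dataset, p),
                     B = bscore(dataset, p),
                     R = rscore(dataset, p))
        tab[[mth]] <- sm$values[cbind(sub$row + 1L, sub$col + 1L)]
      }
    }
    tab
  })
  do.call(rbind, out)
}
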