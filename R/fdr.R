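#' Bayesian FDR estimate at a threshold
#'
#' Estimates the false discovery rate of calling every well whose
#' posterior hit probability strictly exceeds `r`:
#' `sum 1(p > r) (1 - p) / sum 1(p > r)`. When no well exceeds `r` the
#' estimate is undefined and `NA` is returned (distinct from 0).
#'
#' @param hit_prob vector of posterior hit probabilities in `[0, 1]`.
#' @param r threshold in `[0, 1]`; wells with probability exactly `r` are
#'   not called (strict inequality).
#' @return the FDR estimate, or `NA_real_` if nothing is called.
#' @examples
#' estimate_fdr(c(0.9, 0.8, 0.4), 0.5)  # 0.15
#' @export
estimate_fdr <- function(hit_prob, r) {
  if (any(hit_prob < 0 | hit_prob > 1) || anyNA(hit_prob)) {
    ph_stop("hit probabilities must lie in [0, 1]", "platehit_domain_error")
  }
  called <- hit_prob > r
  if (!any(called)) return(NA_real_)
  sum(1 - hit_prob[called]) / sum(called)
}

#' Select a probability threshold controlling Bayesian FDR
#'
#' Searches the grid of observed unique posterior probabilities (the FDR
#' estimator is a step function, so nothing between them matters) for the
#' smallest threshold `r` whose estimated FDR is at or below
#' `target_fdr`; the smallest admissible `r` calls the most wells. If no
#' threshold attains the target, the result is flagged and calls nothing.
#'
#' @param hit_prob vector of posterior hit probabilities.
#' @param target_fdr desired FDR level, in (0, 1).
#' @return an object of class `fdr_result`: `threshold`, `fdr_estimate`,
#'   `n_called`, `calls` (logical vector aligned with `hit_prob`),
#'   `attained`.
#' @export
select_threshold <- function(hit_prob, target_fdr) {
  if (!(target_fdr > 0 && target_fdr < 1)) {
    ph_stop("target_fdr must lie in (0, 1)", "platehit_domain_error")
  }
  grid <- sort(unique(hit_prob))
  for (r in grid) {
    est <- estimate_fdr(hit_prob, r)
    if (!is.na(est) && est <= target_fdr) {
      calls <- hit_prob > r
      return(structure(list(threshold = r, fdr_estimate = est,
                            n_called = sum(calls), calls = calls,
                            attained = TRUE),
                       class = "fdr_result"))
    }
  }
  structure(list(threshold = NA_real_, fdr_estimate = NA_real_,
                 n_called = 0L, calls = rep(FALSE, length(hit_prob)),
                 attained = FALSE),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  if (x$attained) {
    cat(sprintf("<fdr_result> threshold %.6g: %d wells called, estimated FDR %.4f\n",
                x$threshold, x$n_called, x$fdr_estimate))
  } else {
    cat("<fdr_result> target FDR unattainable: nothing called\n")
  }
  invisible(x)
}
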