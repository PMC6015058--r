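#' Model hyperparameters
#'
#' Container for all prior constants and truncation levels of the two-HDP
#' mixture model. The Gaussian atom priors are Normal-inverse-gamma:
#' `mu_c ~ N(mu_c0, sigma_c^2)`, `sigma_c^2 ~ Inv-Gamma(a, b)`, with
#' anchors `mu10` (active channel) and `mu00` (inactive channel) in readout
#' units. `H` is the per-plate (local) truncation and `K >= H` the global
#' truncation of the stick-breaking DP approximations. The mixing
#' proportion has a Beta(`a_pi`, `b_pi`) prior and the four DP
#' concentrations have Gamma priors.
#'
#' @param mu00 prior mean readout of inactive compounds.
#' @param mu10 prior mean readout of active compounds (`mu10 > mu00`).
#' @param a,b inverse-gamma shape/scale for the atom variances.
#' @param a_pi,b_pi Beta prior on the active proportion (default uniform).
#' @param a_alpha,b_alpha Gamma prior on the local DP concentrations.
#' @param a_tau,b_tau Gamma prior on the global DP concentrations.
#' @param H local truncation level (>= 2).
#' @param K global truncation level (>= H).
#' @return an object of class `hts_prior`.
#' @seealso [auto_hyperparameters()] which fills `mu00`, `mu10`, `a`, `b`
#'   from the data.
#' @export
hts_prior <- function(mu00 = NA_real_, mu10 = NA_real_,
                      a = NA_real_, b = NA_real_,
                      a_pi = 1, b_pi = 1,
                      a_alpha = 1, b_alpha = 1,
                      a_tau = 1, b_tau = 1,
                      H = 10L, K = 20L) {
  p <- structure(list(mu00 = mu00, mu10 = mu10, a = a, b = b,
                      a_pi = a_pi, b_pi = b_pi,
                      a_alpha = a_alpha, b_alpha = b_alpha,
                      a_tau = a_tau, b_tau = b_tau,
                      H = as.integer(H), K = as.integer(K)),
                 class = "hts_prior")
  for (nm in c("a_pi", "b_pi", "a_alpha", "b_alpha", "a_tau", "b_tau")) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      ph_stop(sprintf("%s must be positive", nm), "platehit_validation_error")
    }
  }
  if (p$H < 2L) ph_stop("H must be >= 2", "platehit_validation_error")
  if (p$K < p$H) ph_stop("K must be >= H", "platehit_validation_error")
  p
}

#' @export
print.hts_prior <- function(x, ...) {
  cat("<hts_prior>\n")
  cat(sprintf("  atom anchors: mu00 = %g, mu10 = %g\n", x$mu00, x$mu10))
  cat(sprintf("  variance prior: Inv-Gamma(a = %g, b = %g)\n", x$a, x$b))
  cat(sprintf("  pi ~ Beta(%g, %g); alpha ~ Ga(%g, %g); tau ~ Ga(%g, %g)\n",
              x$a_pi, x$b_pi, x$a_alpha, x$b_alpha, x$a_tau, x$b_tau))
  cat(sprintf("  truncation: H = %d, K = %d\n", x$H, x$K))
  invisible(x)
}

## full validation before sampling (anchors must be set by then)
validate_prior <- function(p) {
  for (nm in c("mu00", "mu10", "a", "b")) {
    if (!is.finite(p[[nm]])) {
      ph_stop(sprintf("hyperparameter %s is unset; call auto_hyperparameters()",
                      nm),
              "platehit_validation_error")
    }
  }
  if (p$a <= 0 || p$b <= 0) {
    ph_stop("inverse-gamma a, b must be positive", "platehit_validation_error")
  }
  if (!(p$mu10 > p$mu00)) {
    ph_stop("need mu10 > mu00 (active anchor above inactive anchor)",
            "platehit_validation_error")
  }
  invisible(p)
}

#' Automatic hyperparameter specification from the data
#'
#' Fills the data-dependent hyperparameters from the pooled compound
#' readouts, without using controls. With `mu` the mean and `v` the sample
#' variance of all compound readouts:
#' `mu00 = 0.5 * mu`, `mu10 = 3 * mu00`, and the inverse-gamma constants
#' are chosen so the prior on the atom variances has mean `v` and variance
#' `inv_gamma_var`: `a = v^2 / inv_gamma_var + 2`,
#' `b = v^3 / inv_gamma_var + v`. The default `inv_gamma_var = 1e-4`
#' gives a well-concentrated prior with `a > 2`.
#'
#' @param dataset a [screen_dataset()].
#' @param inv_gamma_var target prior variance of the atom variances.
#' @param prior an [hts_prior()] supplying the remaining constants;
#'   its `mu00`/`mu10`/`a`/`b` are overwritten.
#' @return a fully specified [hts_prior()].
#' @export
auto_hyperparameters <- function(dataset, inv_gamma_var = 1e-4,
                                 prior = hts_prior()) {
  z <- compound_wells(dataset)$readout
  if (length(z) < 2L) {
    ph_stop("need at least 2 compound wells", "platehit_degenerate_data_error")
  }
  v <- var(z)
  if (v == 0) {
    ph_stop("compound readouts have zero variance",
            "platehit_degenerate_data_error")
  }
  mu <- mean(z)
  if (mu <= 0) {
    warning("compound mean is not positive; automatic anchors need ",
            "positive-scale readouts (mu10 would not exceed mu00)")
    ph_stop("compound mean <= 0: set mu00/mu10 manually",
            "platehit_degenerate_data_error")
  }
  prior$mu00 <- 0.5 * mu
  prior$mu10 <- 3 * prior$mu00
  prior$a <- v^2 / inv_gamma_var + 2
  prior$b <- v^3 / inv_gamma_var + v
  validate_prior(prior)
}
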