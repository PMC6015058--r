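#' Stick-breaking weights
#'
#' Converts truncated stick-breaking beta variables into mixture weights:
#' `w_l = v_l * prod_{j<l} (1 - v_j)`, with the final stick forced to 1 so
#' that the weights close to sum exactly 1.
#'
#' @param sticks numeric vector of stick variables in `[0, 1]`; the last
#'   element is treated as 1 regardless of its value.
#' @return weight vector of the same length, summing to 1.
#' @examples
#' stick_weights(c(0.5, 0.5, 1))  # 0.5, 0.25, 0.25
#' @export
stick_weights <- function(sticks) {
  if (any(sticks < 0 | sticks > 1) || anyNA(sticks)) {
    ph_stop("stick variables must lie in [0, 1]", "platehit_domain_error")
  }
  L <- length(sticks)
  w <- numeric(L)
  rem <- 1
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      w[l] <- sticks[l] * rem
      rem <- rem * (1 - sticks[l])
    }
  }
  w[L] <- rem
  w
}

## linear index into the (M, 2, H) local arrays; m 1-based, c in 0:1, h 1-based
map_index <- function(m, c, h, M) m + M * (c + 2 * (h - 1L))

#' Initialize a sampler state
#'
#' Builds a valid Markov chain starting configuration: the top 1% of
#' readouts start active (at least one active and one inactive well
#' guaranteed), local labels and atom maps are uniform, sticks are drawn
#' from their priors, and concentrations sit at their prior means. Fully
#' determined by `seed`.
#'
#' Starting with a small active set is deliberately conservative: wells
#' flip into the active channel quickly wherever the likelihood supports
#' it (the active mixture concentrates on the upper mode), whereas a
#' start with a large active fraction (e.g. everything above the pooled
#' mean) seeds the absorbing mode in which the active channel swallows
#' the upper half of the inactive bulk — at screening-realistic hit rates
#' the chain does not recover from that within practical budgets.
#'
#' Atoms are initialized around their channel anchors with dispersion set
#' by the anchor separation (means `~ N(anchor, (mu10 - mu00)/4)`,
#' variances at `((mu10 - mu00)/2)^2`), and the mixing proportion starts
#' at the thresholded active fraction. Starting instead from unconstrained
#' prior draws leaves the first sweep blind to the anchors (the prior atom
#' variances are as wide as the pooled data), so the chain can fall into
#' the label-swapped mode where the active channel absorbs the inactive
#' bulk; anchoring the start point puts the chain in the basin the priors
#' are designed to select (see the methods vignette).
#'
#' @param dataset a [screen_dataset()].
#' @param prior a fully specified [hts_prior()].
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @return an object of class `hts_state`.
#' @export
init_state <- function(dataset, prior, seed = NULL) {
  validate_prior(prior)
  if (prior$H > 64L) ph_stop("H > 64 is not supported", "platehit_validation_error")
  if (!is.null(seed)) set.seed(seed)
  cw <- compound_wells(dataset)
  z <- cw$readout
  n <- length(z)
  M <- n_plates(dataset)
  H <- prior$H
  K <- prior$K

  k <- min(max(1L, as.integer(ceiling(0.01 * n))), n - 1L)
  b <- integer(n)
  b[order(z, decreasing = TRUE)[seq_len(k)]] <- 1L

  lab <- sample.int(H, n, replace = TRUE)
  map <- array(sample.int(K, M * 2L * H, replace = TRUE), dim = c(M, 2L, H))

  alpha <- rep(prior$a_alpha / prior$b_alpha, 2)
  tau <- rep(prior$a_tau / prior$b_tau, 2)

  v <- array(0, dim = c(M, 2L, H))
  v[, , seq_len(H - 1L)] <- rbeta(M * 2L * (H - 1L), 1, alpha[1L])
  v[, , H] <- 1

  u <- matrix(1, K, 2L)
  u[seq_len(K - 1L), ] <- rbeta((K - 1L) * 2L, 1, tau[1L])

  sep <- prior$mu10 - prior$mu00
  s2 <- matrix((sep / 2)^2, K, 2L)
  mu <- matrix(rnorm(K * 2L,
                     mean = rep(c(prior$mu00, prior$mu10), each = K),
                     sd = sep / 4),
               K, 2L)

  pi0 <- min(max(mean(b), 1 / n), 1 - 1 / n)

  structure(list(pi = pi0, b = b, lab = lab, map = map, v = v, u = u,
                 mu = mu, s2 = s2, alpha = alpha, tau = tau,
                 M = M, H = H, K = K, n = n),
            class = "hts_state")
}

#' @export
print.hts_state <- function(x, ...) {
  cat(sprintf("<hts_state> %d wells on %d plates; H = %d, K = %d; pi = %.3f; %d active\n",
              x$n, x$M, x$H, x$K, x$pi, sum(x$b)))
  invisible(x)
}

## local mixture weights of one plate/channel (channel: 0 inactive, 1 active)
local_weights <- function(state, m, channel) {
  stick_weights(state$v[m, channel + 1L, ])
}

#' Model density of a readout
#'
#' Evaluates the two-channel mixture density implied by a sampler state at
#' plate `m`:
#' `pi * sum_h lambda_mh^(1) N(z; atom) + (1 - pi) * sum_h lambda_mh^(0) N(z; atom)`,
#' where each local cluster h points to its mapped global atom.
#'
#' @param z numeric vector of readout values.
#' @param state an `hts_state`.
#' @param m plate index (1-based).
#' @return density values, strictly positive.
#' @export
mixture_density <- function(z, state, m) {
  dens <- numeric(length(z))
  for (channel in 0:1) {
    w <- local_weights(state, m, channel)
    comp <- numeric(length(z))
    for (h in seq_len(state$H)) {
      k <- state$map[m, channel + 1L, h]
      comp <- comp + w[h] * dnorm(z, state$mu[k, channel + 1L],
                                  sqrt(state$s2[k, channel + 1L]))
    }
    dens <- dens + (if (channel == 1L) state$pi else 1 - state$pi) * comp
  }
  dens
}

#' One Gibbs sweep
#'
#' Performs one full sweep of conjugate conditional updates in fixed
#' order: activity indicators, local labels, local-to-global maps, local
#' and global sticks, atoms, the mixing proportion, and the DP
#' concentrations. Empty clusters and atoms are refreshed from their
#' priors. Consumes R's RNG stream, so a surrounding `set.seed()` makes
#' sweeps reproducible.
#'
#' @param state an `hts_state` from [init_state()] or a previous sweep.
#' @param dataset the [screen_dataset()] the state was built for.
#' @param prior the [hts_prior()] in use.
#' @return the updated `hts_state`.
#' @export
gibbs_step <- function(state, dataset, prior) {
  cw <- compound_wells(dataset)
  upd <- gibbs_sweep_cpp(cw$readout, cw$plate - 1L, state$M,
                         state$pi, state$b, state$lab,
                         as.integer(state$map), as.numeric(state$v),
                         state$u, state$mu, state$s2,
                         state$alpha, state$tau,
                         prior[c("a_pi", "b_pi", "a_alpha", "b_alpha",
                                 "a_tau", "b_tau", "a", "b", "mu00", "mu10")])
  state$pi <- upd$pi
  state$b <- upd$b
  state$lab <- upd$lab
  state$map <- array(upd$map, dim = c(state$M, 2L, state$H))
  state$v <- array(upd$v, dim = c(state$M, 2L, state$H))
  state$u <- upd$u
  state$mu <- upd$mu
  state$s2 <- upd$s2
  state$alpha <- upd$alpha
  state$tau <- upd$tau
  state$p_active <- upd$p_active
  state
}

## expected readout of each channel under the current global weights
channel_means <- function(state) {
  vapply(1:2, function(cc) {
    sum(stick_weights(state$u[, cc]) * state$mu[, cc])
  }, numeric(1))
}

#' Run the Gibbs sampler
#'
#' Fits the two-HDP mixture to a dataset and summarizes the kept
#' iterations. The posterior hit probability of a compound well is the
#' fraction of kept iterations in which its activity indicator was 1.
#' Defaults follow the reference budget of 7000 iterations with a
#' 2000-iteration burn-in, thinned by 5.
#'
#' @param dataset a [screen_dataset()].
#' @param prior a fully specified [hts_prior()]; see
#'   [auto_hyperparameters()].
#' @param n_iter total Gibbs sweeps.
#' @param burn_in sweeps discarded before summarizing (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed controlling the whole run.
#' @param keep_atoms record the per-iteration global atom means.
#' @return an object of class `posterior_summary`: `hit_prob` (data.frame
#'   keyed by plate/row/col with the posterior probabilities; column
#'   `hit_prob` is the Rao-Blackwellized estimate — the average over kept
#'   sweeps of the conditional activity probability, the low-variance
#'   estimator of the same posterior quantity — and `hit_prob_draw` is the
#'   plain fraction of kept sweeps with the indicator at 1), `traces`
#'   (data.frame of per-kept-iteration scalars: `pi`, `alpha0`, `alpha1`,
#'   `tau0`, `tau1`, `chan_mean0`, `chan_mean1`), optional `atom_means`
#'   (kept x K x 2 array), and `n_kept`.
#' @export
run_sampler <- function(dataset, prior, n_iter = 7000L, burn_in = 2000L,
                        thin = 5L, seed = 1L, keep_atoms = FALSE) {
  validate_prior(prior)
  if (!(n_iter > burn_in) || burn_in < 0L || thin < 1L) {
    ph_stop("need n_iter > burn_in >= 0 and thin >= 1",
            "platehit_validation_error")
  }
  state <- init_state(dataset, prior, seed = seed)
  cw <- compound_wells(dataset)
  n <- nrow(cw)
  n_kept_max <- (n_iter - burn_in) %/% thin + 1L
  bsum <- numeric(n)
  rbsum <- numeric(n)
  tr <- matrix(NA_real_, n_kept_max, 7L,
               dimnames = list(NULL, c("pi", "alpha0", "alpha1", "tau0",
                                       "tau1", "chan_mean0", "chan_mean1")))
  atoms <- if (keep_atoms) array(NA_real_, c(n_kept_max, prior$K, 2L)) else NULL
  kept <- 0L
  for (it in seq_len(n_iter)) {
    state <- gibbs_step(state, dataset, prior)
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      bsum <- bsum + state$b
      rbsum <- rbsum + state$p_active
      cm <- channel_means(state)
      tr[kept, ] <- c(state$pi, state$alpha, state$tau, cm)
      if (keep_atoms) atoms[kept, , ] <- state$mu
    }
  }
  hit_prob <- cw[, c("plate_id", "row", "col")]
  hit_prob$hit_prob <- rbsum / kept
  hit_prob$hit_prob_draw <- bsum / kept
  traces <- as.data.frame(tr[seq_len(kept), , drop = FALSE])
  structure(list(hit_prob = hit_prob, traces = traces, n_kept = kept,
                 atom_means = if (keep_atoms) atoms[seq_len(kept), , , drop = FALSE] else NULL,
                 final_state = state),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %d wells, %d kept iterations; mean hit_prob = %.4f\n",
              nrow(x$hit_prob), x$n_kept, mean(x$hit_prob$hit_prob)))
  invisible(x)
}

## Draw a state from the full generative prior (all latents): used by the
## Geweke-style joint-consistency test of the sweep conditionals.
prior_state <- function(dataset, prior) {
  validate_prior(prior)
  cw <- compound_wells(dataset)
  n <- nrow(cw)
  M <- n_plates(dataset)
  H <- prior$H
  K <- prior$K

  pi0 <- rbeta(1, prior$a_pi, prior$b_pi)
  alpha <- rgamma(2, prior$a_alpha, rate = prior$b_alpha)
  tau <- rgamma(2, prior$a_tau, rate = prior$b_tau)

  u <- matrix(1, K, 2L)
  v <- array(1, dim = c(M, 2L, H))
  for (cc in 1:2) {
    if (K > 1L) u[seq_len(K - 1L), cc] <- rbeta(K - 1L, 1, tau[cc])
    if (H > 1L) v[, cc, seq_len(H - 1L)] <- rbeta(M * (H - 1L), 1, alpha[cc])
  }

  s2 <- matrix(1 / rgamma(K * 2L, shape = prior$a, rate = prior$b), K, 2L)
  mu <- matrix(rnorm(K * 2L,
                     mean = rep(c(prior$mu00, prior$mu10), each = K),
                     sd = sqrt(s2)),
               K, 2L)

  map <- array(0L, dim = c(M, 2L, H))
  for (cc in 1:2) {
    gw <- stick_weights(u[, cc])
    map[, cc, ] <- sample.int(K, M * H, replace = TRUE, prob = gw)
  }

  b <- rbinom(n, 1L, pi0)
  lab <- integer(n)
  for (m in seq_len(M)) {
    for (cc in 1:2) {
      sel <- which(cw$plate == m & b == (cc - 1L))
      if (length(sel)) {
        lw <- stick_weights(v[m, cc, ])
        lab[sel] <- sample.int(H, length(sel), replace = TRUE, prob = lw)
      }
    }
  }

  structure(list(pi = pi0, b = b, lab = lab, map = map, v = v, u = u,
                 mu = mu, s2 = s2, alpha = alpha, tau = tau,
                 M = M, H = H, K = K, n = n),
            class = "hts_state")
}

#' Regenerate readouts from a state (prior/posterior checking)
#'
#' Draws new readouts from the emission distribution implied by the
#' current allocations: `z_i ~ N(atom of (b_i, lab_i))`. Used for
#' successive-conditional (Geweke-style) joint-consistency checking of
#' the sampler.
#'
#' @param state an `hts_state`.
#' @param dataset the matching [screen_dataset()]; its compound readouts
#'   are replaced.
#' @return the dataset with regenerated compound readouts.
#' @export
regenerate_readouts <- function(state, dataset) {
  cw <- compound_wells(dataset)
  k <- state$map[cbind(cw$plate, state$b + 1L, state$lab)]
  idx <- cbind(k, state$b + 1L)
  znew <- rnorm(state$n, mean = state$mu[idx], sd = sqrt(state$s2[idx]))
  sel <- dataset$wells$role == "compound"
  dataset$wells$readout[sel] <- znew
  dataset
}
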