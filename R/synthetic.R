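#' Specification of a synthetic screen
#'
#' Describes the generative recipe for a simulated multi-plate screen:
#' hits and non-hits are drawn from four-component log-normal mixtures,
#' permuted uniformly at random across all plate positions, and each plate
#' receives an independent matrix-normal noise draw (separable row/column
#' covariance) emulating within-plate positional artifacts.
#'
#' The default mixture constants are the reference recipe for an
#' activation-type screen on 8 x 10 compound grids: hit component means
#' `{0.20, 0.24, 0.28, 0.32}` with variances `{0.0020, 0.0022, 0.0024,
#' 0.0026}`; non-hit means `{0.10, 0.12, 0.14, 0.16}` with variances
#' `{0.010, 0.011, 0.012, 0.013}`. Component means are means of the
#' log-normal variate itself; component variances are log-scale variances
#' (`sdlog^2`), the reading that reproduces the intended bimodal pooled
#' density (see the methods vignette). Component weights default to
#' uniform.
#'
#' The default noise scale matrices make row effects dominate (compound
#' symmetry with correlation 0.5 across rows, diagonal across columns),
#' with the common scale `s^2 = 0.065` chosen so the per-well noise
#' standard deviation is about 25% of the mean non-hit level (0.13).
#'
#' @param n_plates,n_rows,n_cols plate count and geometry; every well is a
#'   compound well, so `n_compounds = n_plates * n_rows * n_cols`.
#' @param hit_fraction fraction of true hits in (0, 1); the hit count is
#'   `floor(hit_fraction * n_compounds)`, deterministic so that extreme
#'   rates still yield exact truth sets.
#' @param hit_means,hit_vars,nonhit_means,nonhit_vars mixture component
#'   moments (equal-length vectors).
#' @param hit_weights,nonhit_weights component weights (default uniform).
#' @param row_scale,col_scale positive-semidefinite noise scale matrices
#'   (`n_rows x n_rows`, `n_cols x n_cols`).
#' @param noise_multiplier scalar multiplying each noise plate (0 disables
#'   plate effects).
#' @param seed default seed used by [generate_compounds()] /
#'   [simulate_screen()].
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_plates = 1000L, n_rows = 8L, n_cols = 10L,
                           hit_fraction = 0.10,
                           hit_means = c(0.20, 0.24, 0.28, 0.32),
                           hit_vars = c(0.0020, 0.0022, 0.0024, 0.0026),
                           nonhit_means = c(0.10, 0.12, 0.14, 0.16),
                           nonhit_vars = c(0.010, 0.011, 0.012, 0.013),
                           hit_weights = NULL, nonhit_weights = NULL,
                           row_scale = NULL, col_scale = NULL,
                           noise_multiplier = 1, seed = 1L) {
  if (!(hit_fraction > 0 && hit_fraction < 1)) {
    ph_stop("hit_fraction must lie in (0, 1)", "platehit_spec_error")
  }
  if (length(hit_means) != length(hit_vars) ||
      length(nonhit_means) != length(nonhit_vars)) {
    ph_stop("component means and variances must have equal length",
            "platehit_spec_error")
  }
  if (any(hit_means <= 0) || any(nonhit_means <= 0) ||
      any(hit_vars <= 0) || any(nonhit_vars <= 0)) {
    ph_stop("log-normal moment matching needs positive means and variances",
            "platehit_spec_error")
  }
  hit_weights <- hit_weights %||% rep(1 / length(hit_means), length(hit_means))
  nonhit_weights <- nonhit_weights %||%
    rep(1 / length(nonhit_means), length(nonhit_means))
  s2 <- 0.065  # noise sd = s2/2 = 0.0325 ~ 25% of the 0.13 non-hit mean
  if (is.null(row_scale)) {
    row_scale <- s2 * (0.5 * diag(n_rows) + 0.5)
  }
  if (is.null(col_scale)) {
    col_scale <- diag(s2 / 4, n_cols)
  }
  check_psd(row_scale, n_rows, "row_scale")
  check_psd(col_scale, n_cols, "col_scale")
  if (noise_multiplier < 0) {
    ph_stop("noise_multiplier must be >= 0", "platehit_spec_error")
  }
  structure(list(n_plates = as.integer(n_plates), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 n_compounds = as.integer(n_plates) * as.integer(n_rows) *
                   as.integer(n_cols),
                 hit_fraction = hit_fraction,
                 hit_means = hit_means, hit_vars = hit_vars,
                 nonhit_means = nonhit_means, nonhit_vars = nonhit_vars,
                 hit_weights = hit_weights, nonhit_weights = nonhit_weights,
                 row_scale = row_scale, col_scale = col_scale,
                 noise_multiplier = noise_multiplier, seed = as.integer(seed)),
            class = "synthetic_spec")
}

check_psd <- function(m, dim_expected, name) {
  if (!is.matrix(m) || nrow(m) != dim_expected || ncol(m) != dim_expected ||
      max(abs(m - t(m))) > 1e-8) {
    ph_stop(sprintf("%s must be a symmetric %dx%d matrix", name,
                    dim_expected, dim_expected),
            "platehit_spec_error")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    ph_stop(sprintf("%s is not positive semidefinite", name),
            "platehit_decomposition_error")
  }
  invisible(m)
}

## component parameterization: m is the mean of the log-normal variate,
## v its log-scale variance (sdlog^2). meanlog = log(m) - v/2 makes the
## variate mean exactly m. Interpreting v as the variate variance instead
## would give the non-hit components a coefficient of variation near 1,
## destroying the bimodal hit/non-hit structure the recipe emulates (see
## the methods vignette).
lognormal_params <- function(m, v) {
  list(meanlog = log(m) - v / 2, sdlog = sqrt(v))
}

## draw n values from a log-normal mixture given variate-scale moments
rlnorm_mixture <- function(n, means, vars, weights) {
  comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
  p <- lognormal_params(means[comp], vars[comp])
  stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
}

#' Generate compounds and place them on plates
#'
#' Draws `floor(hit_fraction * n)` hits from the hit mixture and the
#' remainder from the non-hit mixture, permutes all compounds uniformly at
#' random over the plate positions, and records the ground-truth labels.
#' No plate noise is added here; see [apply_noise()].
#'
#' @param spec a [synthetic_spec()].
#' @param seed overrides `spec$seed`.
#' @return a [screen_dataset()] with a `truth` column.
#' @export
generate_compounds <- function(spec, seed = spec$seed) {
  set.seed(seed)
  n <- spec$n_compounds
  n_hits <- floor(spec$hit_fraction * n)
  vals <- c(rlnorm_mixture(n_hits, spec$hit_means, spec$hit_vars,
                           spec$hit_weights),
            rlnorm_mixture(n - n_hits, spec$nonhit_means, spec$nonhit_vars,
                           spec$nonhit_weights))
  truth <- rep(c(1L, 0L), c(n_hits, n - n_hits))
  perm <- sample.int(n)
  vals <- vals[perm]
  truth <- truth[perm]

  per_plate <- spec$n_rows * spec$n_cols
  wells <- data.frame(
    plate_id = rep(sprintf("P%05d", seq_len(spec$n_plates)), each = per_plate),
    row = rep(rep(seq_len(spec$n_rows) - 1L, each = spec$n_cols),
              times = spec$n_plates),
    col = rep(seq_len(spec$n_cols) - 1L,
              times = spec$n_plates * spec$n_rows),
    role = "compound",
    readout = vals,
    truth = truth,
    stringsAsFactors = FALSE
  )
  screen_dataset(wells)
}

#' Draw one matrix-normal noise plate
#'
#' Samples from the matrix-normal distribution with zero location and the
#' given row/column scale matrices, via `A G B'` where `A A' = row_scale`,
#' `B B' = col_scale` are symmetric PSD square roots and `G` is a matrix
#' of iid standard normals. Consumes the current RNG stream.
#'
#' @param n_rows,n_cols noise plate geometry.
#' @param row_scale,col_scale symmetric PSD scale matrices.
#' @return an `n_rows x n_cols` noise matrix with mean zero.
#' @export
generate_plate_noise <- function(n_rows, n_cols, row_scale, col_scale) {
  check_psd(row_scale, n_rows, "row_scale")
  check_psd(col_scale, n_cols, "col_scale")
  A <- psd_sqrt(row_scale)
  B <- psd_sqrt(col_scale)
  G <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  A %*% G %*% t(B)
}

psd_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Add plate-effect noise to a dataset
#'
#' Adds an independently drawn matrix-normal noise plate, scaled by
#' `spec$noise_multiplier`, to every plate of the dataset. Truth labels
#' are unchanged. Consumes the current RNG stream (noise plates are drawn
#' sequentially in plate order).
#'
#' @param dataset a [screen_dataset()] whose plates match `spec` geometry.
#' @param spec a [synthetic_spec()].
#' @return the noised [screen_dataset()].
#' @export
apply_noise <- function(dataset, spec) {
  if (any(dataset$geometry$n_rows != spec$n_rows) ||
      any(dataset$geometry$n_cols != spec$n_cols)) {
    ph_stop("dataset geometry does not match the synthetic spec",
            "platehit_shape_error")
  }
  if (spec$noise_multiplier == 0) return(dataset)
  w <- dataset$wells
  idx_by_plate <- split(seq_len(nrow(w)),
                        factor(w$plate_id, levels = dataset$geometry$plate_id))
  for (p in dataset$geometry$plate_id) {
    noise <- spec$noise_multiplier *
      generate_plate_noise(spec$n_rows, spec$n_cols,
                           spec$row_scale, spec$col_scale)
    sel <- idx_by_plate[[p]]
    w$readout[sel] <- w$readout[sel] +
      noise[cbind(w$row[sel] + 1L, w$col[sel] + 1L)]
  }
  dataset$wells <- w
  dataset
}

#' Simulate a full synthetic screen
#'
#' [generate_compounds()] followed by [apply_noise()] under a single seed.
#'
#' @inheritParams generate_compounds
#' @return a [screen_dataset()] with truth labels.
#' @export
simulate_screen <- function(spec, seed = spec$seed) {
  ds <- generate_compounds(spec, seed = seed)
  apply_noise(ds, spec)
}

#' Standard microtiter plate layouts
#'
#' Role layout of the common plate formats with controls in the outer
#' columns: a 96-well plate (8 x 12) keeps 80 compound wells and a
#' 384-well plate (16 x 24) keeps 352 once the first and last columns are
#' reserved for controls (negative on the first, positive on the last).
#'
#' @param format `"96"` or `"384"`.
#' @return a character matrix of roles (`"compound"`, `"neg"`, `"pos"`).
#' @examples
#' sum(standard_plate_layout("96") == "compound")   # 80
#' sum(standard_plate_layout("384") == "compound")  # 352
#' @export
standard_plate_layout <- function(format = c("96", "384")) {
  format <- match.arg(format)
  dims <- if (format == "96") c(8L, 12L) else c(16L, 24L)
  m <- matrix("compound", dims[1], dims[2])
  m[, 1] <- "neg"
  m[, dims[2]] <- "pos"
  m
}
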