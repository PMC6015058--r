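#' Multi-plate screen datasets
#'
#' A `screen_dataset` is an ordered collection of rectangular plates. It is
#' stored as a long-format well table (one row per well) plus a per-plate
#' geometry table. Wells carry a role: `"compound"` for test compounds,
#' `"pos"`/`"neg"` for positive/negative controls. Coordinates are 0-based
#' and row-major; every plate grid must be complete. An optional `truth`
#' column (0/1) marks simulated ground-truth hits and must cover exactly
#' the compound wells.
#'
#' @param wells data.frame with columns `plate_id`, `row`, `col`, `role`,
#'   `readout` and optionally `truth`.
#' @return An object of class `screen_dataset` with elements `wells`
#'   (canonically ordered data.frame) and `geometry` (one row per plate:
#'   `plate_id`, `n_rows`, `n_cols`, `n_compound`).
#' @examples
#' w <- data.frame(plate_id = "P1", row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
#'                 role = "compound", readout = c(1, 2, 3, 4))
#' ds <- screen_dataset(w)
#' n_plates(ds)
#' @export
screen_dataset <- function(wells) {
  required <- c("plate_id", "row", "col", "role", "readout")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols) > 0L) {
    ph_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "platehit_format_error")
  }
  wells <- as.data.frame(wells)[, c(required, intersect("truth", names(wells)))]
  wells$plate_id <- as.character(wells$plate_id)

  if (anyNA(suppressWarnings(as.numeric(wells$readout))) || !is.numeric(wells$readout)) {
    ph_stop("readout column is not numeric", "platehit_parse_error")
  }
  if (any(!is.finite(wells$readout))) {
    ph_stop("non-finite readout values", "platehit_parse_error")
  }
  if (!all(wells$role %in% c("compound", "pos", "neg"))) {
    bad <- setdiff(unique(wells$role), c("compound", "pos", "neg"))
    ph_stop(sprintf("unknown well role(s): %s", paste(bad, collapse = ", ")),
            "platehit_format_error")
  }
  wells$row <- as.integer(wells$row)
  wells$col <- as.integer(wells$col)
  if (anyNA(wells$row) || anyNA(wells$col) ||
      any(wells$row < 0L) || any(wells$col < 0L)) {
    ph_stop("row/col must be non-negative integers", "platehit_format_error")
  }

  key <- paste(wells$plate_id, wells$row, wells$col, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    ph_stop(sprintf("duplicate well coordinates: (%s)",
                    gsub("\r", ",", dup, fixed = TRUE)),
            "platehit_integrity_error")
  }

  ## plates keep first-appearance order; wells become row-major within plate
  pid_levels <- unique(wells$plate_id)
  ord <- order(match(wells$plate_id, pid_levels), wells$row, wells$col)
  wells <- wells[ord, , drop = FALSE]
  rownames(wells) <- NULL

  idx_by_plate <- split(seq_len(nrow(wells)),
                        factor(wells$plate_id, levels = pid_levels))
  geom <- do.call(rbind, lapply(pid_levels, function(p) {
    ii <- idx_by_plate[[p]]
    nr <- max(wells$row[ii]) + 1L
    nc <- max(wells$col[ii]) + 1L
    if (length(ii) != nr * nc) {
      ph_stop(sprintf("plate %s grid incomplete: %d wells for %dx%d geometry",
                      p, length(ii), nr, nc),
              "platehit_integrity_error")
    }
    data.frame(plate_id = p, n_rows = nr, n_cols = nc,
               n_compound = sum(wells$role[ii] == "compound"),
               stringsAsFactors = FALSE)
  }))
  if (any(geom$n_compound < 1L)) {
    ph_stop("every plate needs at least one compound well",
            "platehit_integrity_error")
  }

  if ("truth" %in% names(wells)) {
    cw <- wells$role == "compound"
    if (anyNA(wells$truth[cw]) || !all(wells$truth[cw] %in% c(0, 1))) {
      ph_stop("truth must be 0/1 on every compound well",
              "platehit_integrity_error")
    }
    if (any(!is.na(wells$truth[!cw]))) {
      ph_stop("truth must cover exactly the compound wells (NA on controls)",
              "platehit_integrity_error")
    }
    wells$truth <- as.integer(wells$truth)
  }

  structure(list(wells = wells, geometry = geom), class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> %d plate(s), %d wells (%d compound)%s\n",
              nrow(x$geometry), nrow(x$wells), sum(x$geometry$n_compound),
              if (has_truth(x)) sprintf(", %d true hits",
                                        sum(x$wells$truth, na.rm = TRUE)) else ""))
  invisible(x)
}

#' @rdname screen_dataset
#' @param dataset a `screen_dataset`.
#' @export
n_plates <- function(dataset) nrow(dataset$geometry)

#' @rdname screen_dataset
#' @export
plate_ids <- function(dataset) dataset$geometry$plate_id

#' @rdname screen_dataset
#' @export
has_truth <- function(dataset) "truth" %in% names(dataset$wells)

#' Compound wells in canonical order
#'
#' Returns the compound wells of a dataset as a data.frame in canonical
#' order (plate file order, then row-major), the ordering used by the
#' sampler and by all per-well result vectors.
#'
#' @param dataset a [screen_dataset()].
#' @return data.frame with `plate_id`, `row`, `col`, `readout`, the plate
#'   index `plate` (1-based) and, when present, `truth`.
#' @export
compound_wells <- function(dataset) {
  w <- dataset$wells[dataset$wells$role == "compound", , drop = FALSE]
  w$plate <- match(w$plate_id, dataset$geometry$plate_id)
  rownames(w) <- NULL
  w
}

#' Extract one plate as a matrix
#'
#' @param dataset a [screen_dataset()].
#' @param plate_id plate identifier.
#' @param what `"readout"` or `"role"`.
#' @return an `n_rows x n_cols` matrix.
#' @export
plate_matrix <- function(dataset, plate_id, what = c("readout", "role")) {
  what <- match.arg(what)
  g <- dataset$geometry[dataset$geometry$plate_id == plate_id, ]
  if (nrow(g) != 1L) ph_stop(sprintf("unknown plate: %s", plate_id),
                             "platehit_integrity_error")
  sub <- dataset$wells[dataset$wells$plate_id == plate_id, ]
  m <- matrix(if (what == "readout") NA_real_ else NA_character_,
              g$n_rows, g$n_cols)
  m[cbind(sub$row + 1L, sub$col + 1L)] <- sub[[what]]
  m
}

## compound sub-grid of a plate; must form a complete rectangle
compound_submatrix <- function(dataset, plate_id) {
  sub <- dataset$wells[dataset$wells$plate_id == plate_id &
                         dataset$wells$role == "compound", ]
  rows <- sort(unique(sub$row))
  cols <- sort(unique(sub$col))
  if (nrow(sub) != length(rows) * length(cols)) {
    ph_stop(sprintf("plate %s: compound wells do not form a complete rectangle",
                    plate_id),
            "platehit_integrity_error")
  }
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(sub$row, rows), match(sub$col, cols))] <- sub$readout
  m
}

#' Read a long-format plate table
#'
#' Reads the canonical interchange format: a delimited text file with
#' header `plate_id,row,col,role,readout` and an optional `truth` column.
#' Roles must be `compound`, `pos` or `neg`; coordinates are 0-based.
#' Plates are ordered by first appearance in the file. Extra columns are
#' ignored.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return a [screen_dataset()].
#' @export
read_plates <- function(path, sep = ",") {
  if (!file.exists(path)) {
    ph_stop(sprintf("file not found: %s", path), "platehit_format_error")
  }
  dt <- data.table::fread(path, sep = sep, colClasses = list(character = "plate_id"),
                          data.table = FALSE, showProgress = FALSE)
  required <- c("plate_id", "row", "col", "role", "readout")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L) {
    ph_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "platehit_format_error")
  }
  if (!is.numeric(dt$readout)) {
    ph_stop("readout column is not numeric", "platehit_parse_error")
  }
  screen_dataset(dt)
}

#' Write a plate table
#'
#' Writes a [screen_dataset()] to the long-format CSV interchange format
#' in canonical order, with full double precision (round-trips through
#' [read_plates()] to at least 12 significant digits).
#'
#' @param dataset a [screen_dataset()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_plates <- function(dataset, path, sep = ",") {
  data.table::fwrite(dataset$wells, path, sep = sep)
  invisible(path)
}

#' Write per-well scores alongside the plate table
#'
#' Joins a score table onto a dataset and writes one long-format CSV with
#' deterministic row order (plate file order, then row-major). The score
#' table is keyed by `(plate_id, row, col)` and carries one column per
#' method; every key must exist in the dataset. An empty score table
#' produces a header-only file.
#'
#' @param dataset a [screen_dataset()].
#' @param scores data.frame with `plate_id`, `row`, `col` plus score columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(dataset, scores, path) {
  keycols <- c("plate_id", "row", "col")
  if (!all(keycols %in% names(scores))) {
    ph_stop("score table must have plate_id, row, col key columns",
            "platehit_format_error")
  }
  method_cols <- setdiff(names(scores), keycols)
  w <- dataset$wells
  wkey <- paste(w$plate_id, w$row, w$col, sep = "\r")
  skey <- paste(scores$plate_id, scores$row, scores$col, sep = "\r")
  miss <- !(skey %in% wkey)
  if (any(miss)) {
    ph_stop(sprintf("score key not in dataset: (%s)",
                    gsub("\r", ",", skey[miss][1L], fixed = TRUE)),
            "platehit_integrity_error")
  }
  idx <- match(skey, wkey)
  out <- cbind(w[idx, , drop = FALSE],
               scores[, method_cols, drop = FALSE])
  out <- out[order(idx), , drop = FALSE]   # canonical order
  if (nrow(scores) == 0L) {
    out <- w[0, , drop = FALSE]
    for (mc in method_cols) out[[mc]] <- numeric(0)
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' Per-plate standardization of compound readouts
#'
#' Transforms the compound wells of every plate to sample mean 0 and
#' sample variance 1 (n-1 denominator), the preprocessing used before
#' model fitting on real screens whose raw scale is arbitrary. Control
#' wells pass through untouched. Idempotent up to floating point.
#'
#' @param dataset a [screen_dataset()].
#' @return a standardized [screen_dataset()].
#' @export
standardize_plates <- function(dataset) {
  w <- dataset$wells
  cw <- which(w$role == "compound")
  idx_by_plate <- split(cw, factor(w$plate_id[cw],
                                   levels = dataset$geometry$plate_id))
  for (p in dataset$geometry$plate_id) {
    sel <- idx_by_plate[[p]]
    x <- w$readout[sel]
    if (length(x) < 2L) {
      ph_stop(sprintf("plate %s: need >= 2 compound wells to standardize", p),
              "platehit_degenerate_plate_error")
    }
    s <- sd(x)
    if (s == 0) {
      ph_stop(sprintf("plate %s has zero within-plate variance", p),
              "platehit_degenerate_plate_error")
    }
    w$readout[sel] <- (x - mean(x)) / s
  }
  dataset$wells <- w
  dataset
}
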