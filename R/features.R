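#' Per-pattern total intensity (absorption feature)
#'
#' The transmitted (absorption) feature of pattern `k` is the sum of all its
#' pixel values; low totals mark scan positions where the object absorbed
#' the beam.
#'
#' @param stack a `DiffractionStack`.
#' @return Numeric vector of length `K`, nonnegative.
#' @export
pattern_sum <- function(stack) {
  stopifnot(inherits(stack, "DiffractionStack"))
  colSums(stack$patterns, dims = 2L)
}

#' Center of mass of a diffraction pattern
#'
#' Intensity-weighted mean pixel coordinate: the x component averages the
#' column index, the y component the row index, each weighted by intensity.
#' The deviation of the CoM from the detector center encodes the dominant
#' scattering direction (differential phase contrast).
#'
#' @param pattern `N x M` numeric matrix with positive total intensity.
#' @param index_origin 0 or 1: the coordinate of the first row/column. The
#'   choice only offsets the CoM by a constant, which [standardize_com()]
#'   removes.
#' @return `c(O_x, O_y)` in pixel units.
#' @export
center_of_mass <- function(pattern, index_origin = 0L) {
  tot <- sum(pattern)
  if (tot <= 0) stop("center of mass undefined for a zero-total pattern",
                     call. = FALSE)
  cols <- seq_len(ncol(pattern)) - 1L + index_origin
  rows <- seq_len(nrow(pattern)) - 1L + index_origin
  c(O_x = sum(cols * colSums(pattern)) / tot,
    O_y = sum(rows * rowSums(pattern)) / tot)
}

#' Standardize a K x 2 CoM array to zero mean and unit variance
#'
#' Each column (x and y) is centered by its mean and divided by its
#' population standard deviation, re-expressing every CoM as a vector from
#' the calibrated beam center; this also cancels any constant beam-center
#' offset and the indexing-origin convention. A zero-variance column (all
#' patterns scatter identically) standardizes to zeros and raises a
#' degeneracy flag instead of erroring.
#'
#' @param raw `K x 2` matrix of raw CoM coordinates (`K >= 2`). Rows may be
#'   `NA` (undefined CoM, zero-total pattern): they are excluded from the
#'   moments and standardized to `(0, 0)`.
#' @return Object of class `CoMArray`: `raw`, `standardized` (`K x 2`),
#'   `means`, `stds`, `degenerate` (per-column flag), `n_undefined`.
#' @export
standardize_com <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 2L || nrow(raw) < 2L)
    stop("`raw` must be a K x 2 matrix with K >= 2", call. = FALSE)
  ok <- stats::complete.cases(raw)
  if (!any(ok)) stop("all CoM rows undefined", call. = FALSE)
  mu <- colMeans(raw[ok, , drop = FALSE])
  sg <- sqrt(colMeans(sweep(raw[ok, , drop = FALSE], 2L, mu)^2))
  degenerate <- sg == 0
  std <- sweep(raw, 2L, mu)
  for (j in 1:2) std[, j] <- if (degenerate[j]) 0 else std[, j] / sg[j]
  std[!ok, ] <- 0
  structure(
    list(raw = raw, standardized = std, means = mu, stds = sg,
         degenerate = degenerate, n_undefined = sum(!ok)),
    class = "CoMArray"
  )
}

#' Per-pattern CoM magnitude (scattering-strength feature)
#'
#' Euclidean norm of each standardized CoM vector; large magnitudes mark
#' scan positions with strongly oriented scattering (object edges, phase
#' gradients).
#'
#' @param com a `CoMArray` from [standardize_com()].
#' @return Nonnegative numeric vector of length `K`.
#' @export
com_magnitude <- function(com) {
  stopifnot(inherits(com, "CoMArray"))
  sqrt(rowSums(com$standardized^2))
}

#' Arrange per-pattern values on the scan grid
#'
#' @param values numeric vector, one value per pattern id.
#' @param grid a `ScanGrid`.
#' @param channel feature channel label, one of `"absorption_sum"`,
#'   `"com_magnitude"`, `"dpc"`, `"darkfield_outer"`, `"darkfield_inner"`.
#' @return Object of class `FeatureMap`: `values` (`n_rows x n_cols`, `NA`
#'   at EMPTY cells), `channel`, `filtered`, `logged`.
#' @export
to_grid_map <- function(values, grid,
                        channel = c("absorption_sum", "com_magnitude", "dpc",
                                    "darkfield_outer", "darkfield_inner")) {
  stopifnot(inherits(grid, "ScanGrid"))
  channel <- match.arg(channel)
  if (length(values) != grid$K)
    stop(sprintf("got %d values for %d patterns", length(values), grid$K),
         call. = FALSE)
  m <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  m[grid$position_of] <- values
  structure(list(values = m, channel = channel, filtered = FALSE,
                 logged = FALSE),
            class = "FeatureMap")
}

#' @export
print.FeatureMap <- function(x, ...) {
  cat(sprintf("<FeatureMap> %s, %d x %d%s%s\n", x$channel,
              nrow(x$values), ncol(x$values),
              if (x$filtered) ", 3x3 mean filtered" else "",
              if (x$logged) ", ln scale" else ""))
  invisible(x)
}

#' 3x3 mean filter on a feature map
#'
#' Replaces every cell by the mean of its 3x3 neighborhood to suppress
#' single-position noise before clustering. Edges are replicate-padded;
#' missing (EMPTY) cells are excluded from each averaging window and remain
#' missing in the output.
#'
#' @param map a `FeatureMap`.
#' @return The filtered `FeatureMap` (`filtered = TRUE`).
#' @export
mean_filter_3x3 <- function(map) {
  stopifnot(inherits(map, "FeatureMap"))
  v <- map$values
  nr <- nrow(v); nc <- ncol(v)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    # replicate padding: clamp shifted indices to the grid
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    w <- v[ri, ci, drop = FALSE]
    hit <- !is.na(w)
    acc[hit] <- acc[hit] + w[hit]
    cnt <- cnt + hit
  }
  out <- ifelse(cnt > 0L, acc / cnt, NA_real_)
  out[is.na(v)] <- NA_real_
  map$values <- out
  map$filtered <- TRUE
  map
}

#' Natural-log conditioning of a feature map
#'
#' Applies `v -> ln(max(v, eps))` with `eps` set to 1e-3 times the smallest
#' positive value in the map, so zero cells get a finite floor and the
#' conditioning is independent of the intensity units.
#'
#' @param map a `FeatureMap` with nonnegative values.
#' @return The log-scaled `FeatureMap` (`logged = TRUE`).
#' @export
log_condition <- function(map) {
  stopifnot(inherits(map, "FeatureMap"))
  v <- map$values
  if (any(v < 0, na.rm = TRUE))
    stop("log conditioning requires nonnegative values", call. = FALSE)
  pos <- v[!is.na(v) & v > 0]
  if (length(pos) == 0L)
    stop("cannot log-condition an all-zero map", call. = FALSE)
  eps <- min(pos) * 1e-3
  map$values <- log(pmax(v, eps))
  map$logged <- TRUE
  map
}

#' Export a CoM array as CSV
#'
#' Columns `k` (0-based), `Ox`, `Oy`, `Ox_std`, `Oy_std`; suitable for
#' quiver plotting of scattering directions.
#'
#' @param com a `CoMArray`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_com <- function(com, path) {
  stopifnot(inherits(com, "CoMArray"))
  utils::write.csv(data.frame(
    k = seq_len(nrow(com$raw)) - 1L,
    Ox = com$raw[, 1L], Oy = com$raw[, 2L],
    Ox_std = com$standardized[, 1L], Oy_std = com$standardized[, 2L]),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a feature map as a CSV grid
#'
#' @param map a `FeatureMap`.
#' @param path output CSV path (plain grid of values, `NA` for EMPTY).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "FeatureMap"))
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
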