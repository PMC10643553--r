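#' Construct a diffraction stack
#'
#' A `DiffractionStack` holds `K` far-field diffraction patterns, each an
#' `N x M` matrix of nonnegative photon counts (arbitrary units). Patterns
#' are stored as an `N x M x K` array; pattern `k` is `patterns[, , k]`.
#'
#' @param patterns numeric array of dimension `N x M x K` (a single `N x M`
#'   matrix is promoted to `K = 1`). Negative detector values are clipped to
#'   zero with a warning giving the affected pixel count.
#' @return An object of class `DiffractionStack` with elements `patterns`,
#'   `K`, `N`, `M` and `n_clipped`.
#' @examples
#' s <- diffraction_stack(array(1, c(8, 8, 4)))
#' s$K
#' @export
diffraction_stack <- function(patterns) {
  if (is.matrix(patterns)) patterns <- array(patterns, c(dim(patterns), 1L))
  if (!is.array(patterns) || length(dim(patterns)) != 3L)
    stop("`patterns` must be a 3-D array (N x M x K)", call. = FALSE)
  if (!is.numeric(patterns) || anyNA(patterns) || any(!is.finite(patterns)))
    stop("pattern intensities must be finite numbers", call. = FALSE)
  d <- dim(patterns)
  if (d[3L] < 1L || d[1L] < 2L || d[2L] < 2L)
    stop("need K >= 1 patterns of at least 2 x 2 pixels", call. = FALSE)
  storage.mode(patterns) <- "double"
  n_neg <- sum(patterns < 0)
  if (n_neg > 0L) {
    warning(sprintf("clipped %d negative detector value(s) to 0", n_neg),
            call. = FALSE)
    patterns[patterns < 0] <- 0
  }
  structure(
    list(patterns = patterns, K = d[3L], N = d[1L], M = d[2L],
         n_clipped = n_neg),
    class = "DiffractionStack"
  )
}

#' @export
print.DiffractionStack <- function(x, ...) {
  cat(sprintf("<DiffractionStack> K = %d patterns of %d x %d pixels\n",
              x$K, x$N, x$M))
  cat(sprintf("  total counts: %.4g (mean %.4g per pattern)\n",
              sum(x$patterns), sum(x$patterns) / x$K))
  invisible(x)
}

#' Read a diffraction stack from a TIFF directory
#'
#' Reads the stack layout written by [write_stack()]: one 32-bit float TIFF
#' per pattern plus a `manifest.json` recording the global intensity scale
#' (TIFF storage is normalised to `[0, 1]`) and the pattern order.
#'
#' @param path directory containing `manifest.json` and the pattern TIFFs.
#' @return A [diffraction_stack()] object.
#' @seealso [write_stack()], [read_positions()]
#' @export
read_stack <- function(path) {
  if (!dir.exists(path)) stop("no such stack directory: ", path, call. = FALSE)
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", path, call. = FALSE)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  files <- file.path(path, man$files)
  missing <- !file.exists(files)
  if (any(missing))
    stop("manifest names missing pattern file(s): ",
         paste(man$files[missing], collapse = ", "), call. = FALSE)
  pats <- lapply(files, tiff::readTIFF)
  d <- dim(pats[[1L]])
  if (length(d) != 2L || !all(vapply(pats, function(p)
        identical(dim(p), d), logical(1L))))
    stop("pattern TIFFs must all be 2-D with identical shape", call. = FALSE)
  arr <- array(unlist(pats, use.names = FALSE), c(d, length(pats))) * man$scale
  diffraction_stack(arr)
}

#' Write a diffraction stack as a TIFF directory
#'
#' @param stack a `DiffractionStack`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "DiffractionStack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scale <- max(stack$patterns)
  if (scale <= 0) scale <- 1
  files <- sprintf("pattern_%05d.tif", seq_len(stack$K) - 1L)
  for (k in seq_len(stack$K))
    tiff::writeTIFF(stack$patterns[, , k] / scale, file.path(path, files[k]),
                    bits.per.sample = 32L)
  jsonlite::write_json(
    list(format = "ptyroi-stack-v1", K = stack$K, N = stack$N, M = stack$M,
         scale = scale, files = files),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Crop the central window of every pattern
#'
#' Keeps the central `n x m` window of each pattern. The window origin is
#' `floor((N - n) / 2)`, `floor((M - m) / 2)` (0-based): when the margin is
#' odd the extra row/column is dropped from the high-index side.
#'
#' @param stack a `DiffractionStack`.
#' @param size integer vector `c(n, m)`, the retained window shape.
#' @return The cropped `DiffractionStack`.
#' @examples
#' s <- diffraction_stack(array(runif(512 * 512), c(512, 512, 1)))
#' crop_center(s, c(256, 256))$N
#' @export
crop_center <- function(stack, size) {
  stopifnot(inherits(stack, "DiffractionStack"), length(size) == 2L)
  n <- as.integer(size[1L]); m <- as.integer(size[2L])
  if (n > stack$N || m > stack$M)
    stop(sprintf("crop size %d x %d exceeds pattern size %d x %d",
                 n, m, stack$N, stack$M), call. = FALSE)
  r0 <- (stack$N - n) %/% 2L
  c0 <- (stack$M - m) %/% 2L
  diffraction_stack(stack$patterns[r0 + seq_len(n), c0 + seq_len(m), ,
                                   drop = FALSE])
}

# Snap 1-D coordinates to lattice indices. Returns 0-based index, inferred
# step and origin. Cluster boundaries are gaps > max(gap)/3, which separates
# jitter (small) from true lattice steps even with sparse occupancy.
.snap_axis <- function(v, tolerance) {
  sv <- sort(v)
  gaps <- diff(sv)
  if (length(gaps) == 0L || max(gaps) == 0) {
    return(list(index = rep(0L, length(v)), step = 1, origin = mean(v)))
  }
  thr <- max(gaps) / 3
  brk <- which(gaps > thr)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(sv))
  centers <- vapply(seq_along(starts),
                    function(i) mean(sv[starts[i]:ends[i]]), numeric(1L))
  dd <- diff(centers)
  step <- if (length(dd) == 0L) 1 else stats::median(dd[dd < 1.5 * min(dd)])
  idx <- as.integer(round((v - centers[1L]) / step))
  resid <- abs(v - (centers[1L] + idx * step))
  if (any(resid > tolerance * step))
    stop(sprintf("position(s) off the scan lattice by more than %g of a step",
                 tolerance), call. = FALSE)
  list(index = idx - min(idx), step = step, origin = centers[1L])
}

#' Build a scan grid from physical positions
#'
#' Snaps per-pattern physical positions onto a rectangular raster lattice.
#' Step sizes are inferred per axis from the lattice spacing; grids may be
#' incomplete (EMPTY cells), as in fly scans with varying line lengths.
#' Rows index the slow (vertical, y) axis, columns the fast (horizontal, x)
#' axis; both increase with the coordinate value.
#'
#' @param positions two-column matrix or data frame of `(x, y)` in microns,
#'   one row per pattern id `k = 0 .. K-1` (row order defines the ids).
#' @param tolerance maximum allowed deviation from the lattice, as a
#'   fraction of the step size.
#' @return An object of class `ScanGrid`: `n_rows`, `n_cols`, `step_x`,
#'   `step_y`, `index_of` (`n_rows x n_cols` matrix of 1-based pattern
#'   indices, `NA` for EMPTY cells) and `position_of` (`K x 2` matrix of
#'   1-based `(row, col)`).
#' @examples
#' pos <- expand.grid(x = seq(0, 15, 0.3), y = seq(0, 14, 0.4))
#' g <- build_grid(pos)
#' g$n_rows * g$n_cols  # 1836 scan positions
#' @export
build_grid <- function(positions, tolerance = 0.25) {
  positions <- as.matrix(positions)[, 1:2, drop = FALSE]
  if (nrow(positions) < 1L) stop("need at least one position", call. = FALSE)
  ax <- .snap_axis(positions[, 1L], tolerance)
  ay <- .snap_axis(positions[, 2L], tolerance)
  n_cols <- max(ax$index) + 1L
  n_rows <- max(ay$index) + 1L
  cell <- ay$index * n_cols + ax$index
  if (anyDuplicated(cell))
    stop("scan position collision: two patterns snap to one grid cell",
         call. = FALSE)
  index_of <- matrix(NA_integer_, n_rows, n_cols)
  index_of[cbind(ay$index + 1L, ax$index + 1L)] <- seq_len(nrow(positions))
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         step_x = ax$step, step_y = ay$step,
         index_of = index_of,
         position_of = cbind(row = ay$index + 1L, col = ax$index + 1L),
         K = nrow(positions)),
    class = "ScanGrid"
  )
}

#' @export
print.ScanGrid <- function(x, ...) {
  cat(sprintf(
    "<ScanGrid> %d rows x %d cols (%d patterns, %d EMPTY), step %.4g x %.4g\n",
    x$n_rows, x$n_cols, x$K, sum(is.na(x$index_of)), x$step_x, x$step_y))
  invisible(x)
}

#' Read scan positions from CSV
#'
#' Expects columns `k`, `x_um`, `y_um` (`k` is the 0-based pattern id);
#' rows are returned in `k` order.
#'
#' @param path CSV file path.
#' @return Matrix with columns `x`, `y`, one row per pattern id.
#' @export
read_positions <- function(path) {
  if (!file.exists(path)) stop("no such positions file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("k", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("positions CSV must have columns k, x_um, y_um", call. = FALSE)
  df <- df[order(df$k), , drop = FALSE]
  if (!identical(as.integer(df$k), seq_len(nrow(df)) - 1L))
    stop("pattern ids must be 0 .. K-1, each exactly once", call. = FALSE)
  cbind(x = df$x_um, y = df$y_um)
}

#' Write an RoI selection to CSV + JSON
#'
#' Writes one CSV row per occupied grid cell (`k`, `row`, `col`, `selected`,
#' `provenance`; `k`, `row`, `col` 0-based, provenance tags `;`-joined) and
#' a JSON summary with selection counts, retained fraction and the mask's
#' configuration echo.
#'
#' @param mask an `RoIMask` (see [roi_mask()]).
#' @param grid the matching `ScanGrid`.
#' @param path output CSV path; the summary is written alongside with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_roi <- function(mask, grid, path) {
  stopifnot(inherits(mask, "RoIMask"), inherits(grid, "ScanGrid"))
  if (!identical(dim(mask$selected), dim(grid$index_of)))
    stop("mask dimensions do not match grid", call. = FALSE)
  occ <- which(!is.na(grid$index_of), arr.ind = TRUE)
  k <- grid$index_of[occ]
  ord <- order(k)
  occ <- occ[ord, , drop = FALSE]; k <- k[ord]
  df <- data.frame(
    k = k - 1L, row = occ[, 1L] - 1L, col = occ[, 2L] - 1L,
    selected = as.integer(mask$selected[occ]),
    provenance = vapply(mask$provenance[occ],
                        function(p) paste(p, collapse = ";"), character(1L)))
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write RoI file: ", conditionMessage(ok),
                        call. = FALSE)
  jsonlite::write_json(
    list(K = grid$K, n_selected = sum(df$selected),
         retained_pct = retained_fraction(mask, grid),
         config = mask$config),
    sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(path)
}

#' Read an RoI selection written by [write_roi()]
#'
#' @param path CSV path.
#' @param grid the matching `ScanGrid`.
#' @return An `RoIMask`.
#' @export
read_roi <- function(path, grid) {
  df <- utils::read.csv(path, colClasses = c(provenance = "character"))
  sel <- matrix(FALSE, grid$n_rows, grid$n_cols)
  prov <- empty_provenance(grid$n_rows, grid$n_cols)
  ij <- cbind(df$row + 1L, df$col + 1L)
  sel[ij] <- df$selected == 1L
  prov[ij] <- lapply(df$provenance, function(p)
    if (nzchar(p)) strsplit(p, ";", fixed = TRUE)[[1L]] else character(0L))
  roi_mask(sel, prov)
}
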