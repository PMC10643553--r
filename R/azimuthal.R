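#' Specify an azimuthal segmentation of the detector
#'
#' Partitions detector pixels into `n` angular wedges of width
#' `theta = 360 / n` degrees about a center, measured counter-clockwise
#' from `origin_angle` (0 = +x axis, i.e. increasing column index; the y
#' axis points up, against the row index, so angles follow the usual
#' mathematical convention).
#'
#' @param n_segments number of wedges (`>= 1`).
#' @param center `(row, col)` of the wedge apex in 0-based pixel
#'   coordinates; `NULL` (default) uses the geometric pattern center
#'   `((N-1)/2, (M-1)/2)`. Supply a calibrated beam center if available.
#' @param origin_angle angular origin in degrees.
#' @return Object of class `SegmentSpec`.
#' @export
segment_spec <- function(n_segments, center = NULL, origin_angle = 0) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("need at least one segment", call. = FALSE)
  structure(list(n_segments = n_segments, theta = 360 / n_segments,
                 center = center, origin_angle = origin_angle),
            class = "SegmentSpec")
}

#' Build azimuthal segment masks for a pattern shape
#'
#' Pixel `(j, i)` joins segment `s` iff its angle about the center, wrapped
#' to `[0, 360)`, lies in the half-open bin `[s * theta, (s + 1) * theta)`.
#' The exact-center pixel (angle undefined) joins segment 0. Half-open bins
#' make the masks an exact partition: every pixel belongs to exactly one
#' segment, so per-segment sums conserve the pattern total.
#'
#' @param shape `c(N, M)` pattern shape in pixels.
#' @param spec a [segment_spec()].
#' @return Object of class `SegmentMasks`: `masks` (list of `N x M` logical
#'   matrices), `labels` (`N x M` integer matrix of 1-based segment ids),
#'   `spec`.
#' @export
make_segments <- function(shape, spec) {
  stopifnot(inherits(spec, "SegmentSpec"), length(shape) == 2L)
  N <- as.integer(shape[1L]); M <- as.integer(shape[2L])
  ctr <- if (is.null(spec$center)) c((N - 1) / 2, (M - 1) / 2) else spec$center
  dx <- matrix(rep(seq_len(M) - 1 - ctr[2L], each = N), N, M)
  dy <- matrix(rep(-(seq_len(N) - 1 - ctr[1L]), M), N, M)  # y up
  # bin in turns: atan2 is exact on the axes/diagonals, so pixels lying on
  # wedge boundaries bin exactly and the partition is rotation-consistent
  turns <- (atan2(dy, dx) / (2 * pi) - spec$origin_angle / 360) %% 1
  seg <- pmin(floor(turns * spec$n_segments), spec$n_segments - 1L) + 1L
  seg[dx == 0 & dy == 0] <- 1L
  masks <- lapply(seq_len(spec$n_segments), function(s) seg == s)
  structure(list(masks = masks, labels = seg, spec = spec),
            class = "SegmentMasks")
}

#' Per-segment sums and centers of mass
#'
#' For every pattern `k` and wedge `s`: the masked intensity total
#' `T_s^k` and the masked CoM in full-frame pixel coordinates (so that the
#' intensity-weighted average of the segment CoMs recombines exactly to the
#' whole-pattern CoM). A dark segment (`T_s^k = 0`) has an undefined CoM,
#' marked `NA`.
#'
#' @param stack a `DiffractionStack`.
#' @param masks a `SegmentMasks` matching the pattern shape.
#' @param index_origin 0 or 1, as in [center_of_mass()].
#' @return List with `T` (`n_segments x K` totals), `com_x`, `com_y`
#'   (`n_segments x K`, `NA` where undefined) and `n_segments`.
#' @export
segment_features <- function(stack, masks, index_origin = 0L) {
  stopifnot(inherits(stack, "DiffractionStack"), inherits(masks, "SegmentMasks"))
  if (!identical(dim(masks$labels), c(stack$N, stack$M)))
    stop("segment masks do not match pattern shape", call. = FALSE)
  n_seg <- masks$spec$n_segments
  P <- matrix(stack$patterns, stack$N * stack$M, stack$K)
  cc <- matrix(rep(seq_len(stack$M) - 1L + index_origin, each = stack$N),
               stack$N, stack$M)
  rc <- matrix(rep(seq_len(stack$N) - 1L + index_origin, stack$M),
               stack$N, stack$M)
  S <- vapply(masks$masks, as.numeric, numeric(stack$N * stack$M))  # NM x S
  tot <- crossprod(S, P)                      # n_seg x K? -> t(S) %*% P
  sx <- crossprod(S * as.vector(cc), P)
  sy <- crossprod(S * as.vector(rc), P)
  dark <- tot == 0
  com_x <- ifelse(dark, NA_real_, sx / tot)
  com_y <- ifelse(dark, NA_real_, sy / tot)
  list(T = tot, com_x = com_x, com_y = com_y, n_segments = n_seg)
}

#' Export segment masks as a labeled integer image
#'
#' Writes the 1-based segment label of every pixel as a CSV grid for visual
#' verification of the wedge geometry.
#'
#' @param masks a `SegmentMasks`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segment_labels <- function(masks, path) {
  stopifnot(inherits(masks, "SegmentMasks"))
  utils::write.table(masks$labels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
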