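#' STXM absorption-contrast map
#'
#' Scanning transmission X-ray microscopy contrast: the total transmitted
#' intensity of each pattern mapped onto its scan position. Identical by
#' definition to the absorption-sum feature map.
#'
#' @param stack a `DiffractionStack`.
#' @param grid the matching `ScanGrid`.
#' @return A `FeatureMap` with channel `"absorption_sum"`.
#' @export
stxm_map <- function(stack, grid) {
  to_grid_map(pattern_sum(stack), grid, "absorption_sum")
}

#' Hilbert differential phase-contrast map
#'
#' Horizontal asymmetry of each pattern: the normalized difference between
#' the intensity on the right and left halves of the detector,
#' `(right - left) / total`, the computational analog of a Hilbert split
#' detector. The exact-center column (odd `M`) is split evenly between the
#' halves, contributing zero net signal. Values lie in `[-1, 1]`;
#' zero-total patterns map to 0 (their count is recorded in the
#' `n_undefined` attribute).
#'
#' @param stack a `DiffractionStack`.
#' @param grid the matching `ScanGrid`.
#' @return A signed `FeatureMap` with channel `"dpc"`.
#' @export
hdpc_map <- function(stack, grid) {
  cx <- (stack$M - 1) / 2
  w <- sign(seq_len(stack$M) - 1 - cx)   # -1 left, +1 right, 0 center col
  tot <- pattern_sum(stack)
  num <- vapply(seq_len(stack$K),
                function(k) sum(colSums(stack$patterns[, , k]) * w),
                numeric(1L))
  vals <- ifelse(tot > 0, num / pmax(tot, .Machine$double.xmin), 0)
  map <- to_grid_map(vals, grid, "dpc")
  attr(map, "n_undefined") <- sum(tot == 0)
  map
}

#' Suggest a dark-field mask radius
#'
#' Smallest radius (about the geometric pattern center) whose disk
#' encloses at least `fraction` of the stack-mean pattern's intensity —
#' i.e. a disk containing the direct (unscattered) beam.
#'
#' @param stack a `DiffractionStack`.
#' @param fraction intensity fraction to enclose (default 0.99).
#' @return Radius in pixels.
#' @export
suggest_radius <- function(stack, fraction = 0.99) {
  stopifnot(fraction > 0, fraction <= 1)
  mp <- apply(stack$patterns, c(1L, 2L), mean)
  ctr <- c((stack$N - 1) / 2, (stack$M - 1) / 2)
  d <- sqrt(outer((seq_len(stack$N) - 1 - ctr[1L])^2,
                  (seq_len(stack$M) - 1 - ctr[2L])^2, `+`))
  ord <- order(d)
  cum <- cumsum(mp[ord])
  d[ord][which(cum >= fraction * sum(mp))[1L]]
}

#' Computational dark-field / bright-field maps
#'
#' Splits every pattern by a circular mask at the detector center: the
#' inner disk holds the direct transmitted beam (absorption sensitivity,
#' identical in character to STXM), the outside holds the high-frequency
#' scattering signal (dark-field). `inner + outer` equals the pattern
#' total exactly for every pattern.
#'
#' @param stack a `DiffractionStack`.
#' @param grid the matching `ScanGrid`.
#' @param radius mask radius in pixels (see [suggest_radius()]).
#' @param center `(row, col)` mask center, 0-based; default the geometric
#'   pattern center.
#' @return List of two `FeatureMap`s, `inner` and `outer`.
#' @export
darkfield_maps <- function(stack, grid, radius, center = NULL) {
  stopifnot(radius > 0)
  ctr <- if (is.null(center)) c((stack$N - 1) / 2, (stack$M - 1) / 2)
         else center
  d <- sqrt(outer((seq_len(stack$N) - 1 - ctr[1L])^2,
                  (seq_len(stack$M) - 1 - ctr[2L])^2, `+`))
  inside <- as.numeric(d <= radius)
  P <- matrix(stack$patterns, stack$N * stack$M, stack$K)
  inner <- as.numeric(crossprod(inside, P))
  outer_ <- pattern_sum(stack) - inner
  list(inner = to_grid_map(inner, grid, "darkfield_inner"),
       outer = to_grid_map(outer_, grid, "darkfield_outer"))
}

#' Baseline RoI estimate from a conventional contrast map
#'
#' Applies the same exact two-means clustering as the main pipeline
#' directly to a conventional contrast map: HDPC clusters the absolute
#' asymmetry and keeps the higher cluster, STXM keeps the lower
#' (absorbing) cluster, dark-field keeps the higher (scattering) cluster.
#' The map is clustered as given; condition it first (e.g.
#' [mean_filter_3x3()]) if desired.
#'
#' @param map a `FeatureMap` (for `"darkfield"`, the `outer` map).
#' @param method one of `"stxm"`, `"hdpc"`, `"darkfield"`.
#' @return An `RoIMask` tagged with the method name.
#' @export
baseline_roi <- function(map, method = c("stxm", "hdpc", "darkfield")) {
  method <- match.arg(method)
  stopifnot(inherits(map, "FeatureMap"))
  if (method == "hdpc") {
    map$values <- abs(map$values)
    return(.cluster_map(map, "higher", "hdpc",
                        config = list(rule = "hdpc", select = "higher")))
  }
  if (method == "stxm")
    .cluster_map(map, "lower", "stxm",
                 config = list(rule = "stxm", select = "lower"))
  else
    .cluster_map(map, "higher", "darkfield",
                 config = list(rule = "darkfield", select = "higher"))
}
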