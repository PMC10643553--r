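#' Create a provenance matrix with no tags
#'
#' @param n_rows,n_cols grid shape.
#' @return `n_rows x n_cols` matrix of empty character vectors.
#' @export
empty_provenance <- function(n_rows, n_cols) {
  matrix(rep(list(character(0L)), n_rows * n_cols), n_rows, n_cols)
}

#' Construct an RoI mask
#'
#' A boolean selection per scan-grid cell plus, for every selected cell,
#' the provenance tags saying which modality (absorption/scattering),
#' segment, or post-processing step (`border`, `fill`) flagged it. A cell
#' is selected iff its provenance is nonempty.
#'
#' @param selected logical matrix (grid shape).
#' @param provenance matrix of character vectors (tags per cell); `NULL`
#'   tags every selected cell `"manual"`.
#' @param config list echoing the parameters that produced the mask.
#' @return Object of class `RoIMask`.
#' @export
roi_mask <- function(selected, provenance = NULL, config = list()) {
  stopifnot(is.logical(selected), is.matrix(selected))
  if (is.null(provenance)) {
    provenance <- empty_provenance(nrow(selected), ncol(selected))
    provenance[selected] <- list("manual")
  }
  stopifnot(identical(dim(provenance), dim(selected)))
  has_tag <- matrix(lengths(provenance) > 0L, nrow(selected))
  if (!identical(unname(has_tag), unname(selected)))
    stop("RoIMask invariant violated: selected iff provenance nonempty",
         call. = FALSE)
  structure(list(selected = selected, provenance = provenance,
                 config = config),
            class = "RoIMask")
}

#' @export
print.RoIMask <- function(x, ...) {
  cat(sprintf("<RoIMask> %d x %d grid, %d cell(s) selected\n",
              nrow(x$selected), ncol(x$selected), sum(x$selected)))
  invisible(x)
}

.empty_roi <- function(grid, config = list())
  roi_mask(matrix(FALSE, grid$n_rows, grid$n_cols), config = config)

#' Exact two-cluster k-means on 1-D data
#'
#' For one-dimensional data the optimal 2-means partition is an interval
#' split of the sorted values, so the global optimum is found exactly by
#' scanning all `n - 1` thresholds — deterministic and seed-free. A Lloyd
#' mode (`stats::kmeans`, k-means++-style restarts) is retained for parity
#' experiments; it can only match, never beat, the exact scan.
#'
#' @param values numeric vector (`>= 2` finite values, not all equal).
#' @param n_iter maximum Lloyd iterations (exact mode ignores it).
#' @param seed RNG seed for Lloyd restarts (exact mode ignores it).
#' @param method `"exact"` (default) or `"lloyd"`.
#' @return Object of class `ClusterResult`: `labels` (0 = lower-centroid
#'   cluster, 1 = higher), `centroids` (`c(lower, higher)`), `inertia`
#'   (within-cluster sum of squares), `threshold` (midpoint separating the
#'   clusters).
#' @export
two_means_1d <- function(values, n_iter = 10L, seed = 0L,
                         method = c("exact", "lloyd")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values) || any(!is.finite(values)))
    stop("need >= 2 finite values", call. = FALSE)
  if (max(values) == min(values))
    stop("degenerate clustering: all values equal", call. = FALSE)
  if (method == "lloyd") {
    set.seed(seed)
    km <- stats::kmeans(values, centers = 2L, iter.max = n_iter, nstart = 10L)
    hi <- which.max(km$centers)
    return(structure(list(labels = as.integer(km$cluster == hi),
                          centroids = sort(as.numeric(km$centers)),
                          inertia = km$tot.withinss,
                          threshold = mean(km$centers)),
                     class = "ClusterResult"))
  }
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  cs <- cumsum(v); cq <- cumsum(v^2)
  i <- seq_len(n - 1L)
  # within-cluster SS of v[1..i] and v[(i+1)..n]
  sse_lo <- cq[i] - cs[i]^2 / i
  sse_hi <- (cq[n] - cq[i]) - (cs[n] - cs[i])^2 / (n - i)
  tot <- sse_lo + sse_hi
  split <- which.min(tot)
  labels_sorted <- as.integer(seq_len(n) > split)
  labels <- integer(n)
  labels[ord] <- labels_sorted
  centroids <- c(cs[split] / split, (cs[n] - cs[split]) / (n - split))
  structure(list(labels = labels, centroids = centroids,
                 inertia = tot[split],
                 threshold = (v[split] + v[split + 1L]) / 2),
            class = "ClusterResult")
}

# Cluster the occupied cells of a conditioned map and select one cluster.
.cluster_map <- function(map, select, tag, config = list()) {
  occ <- !is.na(map$values)
  vals <- map$values[occ]
  res <- tryCatch(two_means_1d(vals),
                  error = function(e) e)
  sel <- matrix(FALSE, nrow(map$values), ncol(map$values))
  if (inherits(res, "error")) {
    warning("no RoI found on channel '", map$channel, "': ",
            conditionMessage(res), call. = FALSE)
    return(.empty_roi(list(n_rows = nrow(sel), n_cols = ncol(sel)), config))
  }
  want <- if (select == "lower") 0L else 1L
  sel[occ] <- res$labels == want
  prov <- empty_provenance(nrow(sel), ncol(sel))
  prov[sel] <- list(tag)
  roi_mask(sel, prov, config)
}

#' RoI from an absorption-contrast map
#'
#' Two-means the conditioned per-position intensity totals and selects the
#' LOWER-centroid cluster: low transmission means the beam was absorbed by
#' the object, so those scan positions belong to the RoI.
#'
#' @param map a conditioned `FeatureMap` with channel `"absorption_sum"`.
#' @param tag provenance tag for selected cells.
#' @return An `RoIMask`; empty (with a warning) if clustering is degenerate.
#' @export
roi_from_absorption <- function(map, tag = "absorption") {
  stopifnot(inherits(map, "FeatureMap"))
  if (map$channel != "absorption_sum")
    stop("absorption rule needs channel 'absorption_sum'", call. = FALSE)
  .cluster_map(map, "lower", tag,
               config = list(rule = "absorption", select = "lower"))
}

#' RoI from a scattering (CoM magnitude) map
#'
#' Two-means the conditioned CoM magnitudes and selects the HIGHER-centroid
#' cluster: strong oriented scattering marks phase gradients and object
#' outlines.
#'
#' @param map a conditioned `FeatureMap` with channel `"com_magnitude"`.
#' @param tag provenance tag for selected cells.
#' @return An `RoIMask`; empty (with a warning) if clustering is degenerate.
#' @export
roi_from_scattering <- function(map, tag = "scattering") {
  stopifnot(inherits(map, "FeatureMap"))
  if (map$channel != "com_magnitude")
    stop("scattering rule needs channel 'com_magnitude'", call. = FALSE)
  .cluster_map(map, "higher", tag,
               config = list(rule = "scattering", select = "higher"))
}

#' Union of two RoI masks
#'
#' Cell-wise OR, counting doubly-flagged positions once; provenance tag
#' sets are merged.
#'
#' @param a,b `RoIMask`s on the same grid.
#' @return The combined `RoIMask`.
#' @export
combine_union <- function(a, b) {
  stopifnot(inherits(a, "RoIMask"), inherits(b, "RoIMask"))
  if (!identical(dim(a$selected), dim(b$selected)))
    stop("cannot union masks on different grids", call. = FALSE)
  sel <- a$selected | b$selected
  prov <- empty_provenance(nrow(sel), ncol(sel))
  prov[] <- mapply(function(pa, pb) union(pa, pb), a$provenance, b$provenance,
                   SIMPLIFY = FALSE)
  roi_mask(sel, prov, config = c(a$config, b$config))
}

# Whole-pattern CoM per pattern; NA rows where the pattern total is zero.
stack_com <- function(stack, index_origin = 0L) {
  t(vapply(seq_len(stack$K), function(k) {
    p <- stack$patterns[, , k]
    if (sum(p) <= 0) return(c(NA_real_, NA_real_))
    center_of_mass(p, index_origin)
  }, numeric(2L)))
}

# One segment's absorption + scattering RoI: condition both maps, apply
# both cluster rules, union. Degeneracies downgrade to an empty mask.
.segment_roi <- function(T_k, mag_k, grid, log_abs, log_mag, tag_abs, tag_sct) {
  condition <- function(map, logged) {
    map <- mean_filter_3x3(map)
    if (logged) map <- log_condition(map)
    map
  }
  abs_mask <- tryCatch(
    roi_from_absorption(condition(to_grid_map(T_k, grid, "absorption_sum"),
                                  log_abs),
                        tag = tag_abs),
    error = function(e) {
      warning("absorption channel skipped: ", conditionMessage(e),
              call. = FALSE)
      .empty_roi(grid)
    })
  sct_mask <- tryCatch(
    roi_from_scattering(condition(to_grid_map(mag_k, grid, "com_magnitude"),
                                  log_mag),
                        tag = tag_sct),
    error = function(e) {
      warning("scattering channel skipped: ", conditionMessage(e),
              call. = FALSE)
      .empty_roi(grid)
    })
  combine_union(abs_mask, sct_mask)
}

#' Full RoI classification pipeline
#'
#' With `n_segments = 1` this is the whole-pattern recipe: per-position
#' intensity totals and standardized CoM magnitudes are gridded, 3x3
#' mean-filtered, natural-log scaled (optional), each two-means clustered
#' (absorption rule: lower cluster; scattering rule: higher cluster), and
#' the two selections unioned. With `n_segments > 1` every diffraction
#' pattern is first split into azimuthal wedges; the same recipe runs on
#' each wedge's totals and CoMs (standardized per wedge across scan
#' positions), and the final mask is the OR over all wedges — this resolves
#' anisotropic scattering from features smaller than the beam, which the
#' whole-pattern CoM averages out. Dark segments (zero total) contribute a
#' standardized CoM of `(0, 0)`.
#'
#' Conditioning before clustering is 3x3 mean filter for both channels,
#' then natural log on the absorption totals only (default): totals are
#' strictly positive with multiplicative (Beer-Lambert) contrast, so the
#' log linearizes absorption, while standardized CoM magnitudes are
#' already dimensionless with a noise floor near zero that a log stretch
#' would inflate into a spurious background split. Both flags are
#' switchable.
#'
#' @param stack a `DiffractionStack`.
#' @param grid the matching `ScanGrid`.
#' @param n_segments number of azimuthal wedges (1 = no segmentation).
#' @param log_abs natural-log conditioning of the absorption channel.
#' @param log_mag natural-log conditioning of the CoM-magnitude channel.
#' @param center,origin_angle wedge geometry, see [segment_spec()].
#' @param index_origin pixel indexing origin for the CoM (immaterial after
#'   standardization).
#' @return An `RoIMask` with per-cell provenance
#'   (`absorption`/`scattering`, suffixed `:s<i>` per wedge when
#'   `n_segments > 1`).
#' @export
run_pipeline <- function(stack, grid, n_segments = 1L, log_abs = TRUE,
                         log_mag = FALSE, center = NULL, origin_angle = 0,
                         index_origin = 0L) {
  stopifnot(inherits(stack, "DiffractionStack"), inherits(grid, "ScanGrid"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop("need n_segments >= 1", call. = FALSE)
  if (stack$K != grid$K)
    stop("stack and grid disagree on the number of patterns", call. = FALSE)
  cfg <- list(n_segments = n_segments, log_abs = log_abs, log_mag = log_mag,
              origin_angle = origin_angle)
  if (n_segments == 1L) {
    raw <- stack_com(stack, index_origin)
    mag <- if (all(is.na(raw)))
      rep(0, stack$K)
    else
      com_magnitude(standardize_com(raw))
    out <- .segment_roi(pattern_sum(stack), mag, grid, log_abs, log_mag,
                        "absorption", "scattering")
  } else {
    masks <- make_segments(c(stack$N, stack$M),
                           segment_spec(n_segments, center, origin_angle))
    sf <- segment_features(stack, masks, index_origin)
    out <- .empty_roi(grid)
    for (s in seq_len(n_segments)) {
      raw <- cbind(sf$com_x[s, ], sf$com_y[s, ])
      mag <- if (all(is.na(raw)))
        rep(0, stack$K)
      else
        com_magnitude(standardize_com(raw))
      out <- combine_union(
        out,
        .segment_roi(sf$T[s, ], mag, grid, log_abs, log_mag,
                     sprintf("absorption:s%d", s - 1L),
                     sprintf("scattering:s%d", s - 1L)))
    }
  }
  out$config <- cfg
  out
}
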