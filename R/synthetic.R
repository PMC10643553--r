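# Swap quadrants so the DC term sits at the (near-)center pixel.
.fftshift2 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1L + n %/% 2L) %% n) + 1L,
    ((seq_len(p) - 1L + p %/% 2L) %% p) + 1L]
}

.disk_indices <- function(size, cy, cx, r) {
  dy <- outer((seq_len(size) - 1 - cy)^2, (seq_len(size) - 1 - cx)^2, `+`)
  which(dy <= r^2)
}

# Pixels inside an ellipse with semi-major a (along orientation theta) and
# semi-minor a/aspect; aspect = 1 gives a disk.
.ellipse_indices <- function(size, cy, cx, a, aspect, theta) {
  yy <- matrix(rep(seq_len(size) - 1 - cy, size), size, size)
  xx <- matrix(rep(seq_len(size) - 1 - cx, each = size), size, size)
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  which((u / a)^2 + (v * aspect / a)^2 <= 1)
}

#' Build a synthetic scanning-diffraction scene
#'
#' Constructs a labeled test scene with the structure the classifier
#' assumes: a large absorbing main particle plus phase-only satellite
#' particles smaller than the probe footprint, rastered by a circular
#' probe on a regular grid. The `"reference"` preset uses a 160x160 pixel
#' object, a circular-aperture probe of diameter 20 px inside a 64x64
#' window, a main disk of radius 25 px (amplitude transmission 0.5, phase
#' 0.5 rad), three phase-only elliptical satellites (semi-axes 4 x 2 px,
#' phase 0.9 rad, distinct orientations — anisotropic scatterers in the
#' manner of plate-like nanoparticles, so their far-field signal is an
#' oriented streak) placed clear of the main disk (positions and
#' orientations jittered by `seed`), a 24 x 24 scan grid with 4 px steps,
#' and an expected 2e5 photons per pattern, which puts the Poisson noise
#' at an estimated SNR of about 6.4 (see [estimate_snr()]).
#' `"phase_disk"` replaces the main disk with a pure-phase one and drops
#' the satellites (no absorption contrast at all); `"empty"` has no
#' particles. Satellite orientations are fixed scene properties (the
#' per-wedge visibility of a streak depends on where it falls relative to
#' wedge boundaries); positions are jittered by up to 3 px by `seed`.
#'
#' @param preset `"reference"`, `"phase_disk"` or `"empty"`.
#' @param seed integer controlling satellite placement jitter.
#' @param ... overrides for the preset fields (`object_size`, `window`,
#'   `probe_diameter`, `grid_n`, `step`, `photons`, `particles` — a data
#'   frame with columns `cy`, `cx`, `radius` (semi-major axis, px),
#'   `aspect` (major/minor ratio, 1 = disk), `theta` (orientation, rad),
#'   `amplitude`, `phase`, `kind`).
#' @return Object of class `SyntheticScene`: `object` (complex
#'   transmission, `|t| <= 1`), `probe` (complex), `particles`, `grid`
#'   (a `ScanGrid`), `offsets` (`K x 2`, 0-based window origins),
#'   `window`, `probe_diameter`, `photons`, `preset`, `seed`.
#' @export
make_scene <- function(preset = c("reference", "phase_disk", "empty"),
                       seed = 0L, ...) {
  preset <- match.arg(preset)
  p <- list(object_size = 160L, window = 64L, probe_diameter = 20,
            grid_n = 24L, step = 4L, photons = 2e5)
  sat_base <- data.frame(cy = c(38, 42, 120), cx = c(38, 120, 40),
                         radius = 4, aspect = 2,
                         theta = c(0.3, 1.4, 2.4), amplitude = 1,
                         phase = 0.9, kind = "satellite")
  set.seed(as.integer(seed))
  jit <- matrix(sample(-3:3, 6L, replace = TRUE), 3L, 2L)
  main <- data.frame(cy = 80, cx = 80, radius = 25, aspect = 1, theta = 0,
                     amplitude = 0.5, phase = 0.5, kind = "main")
  p$particles <- switch(preset,
    reference = rbind(
      main,
      within(sat_base, {
        cy <- cy + jit[, 1L]; cx <- cx + jit[, 2L]
      })),
    phase_disk = within(main, amplitude <- 1),
    empty = main[0L, ])
  over <- list(...)
  p[names(over)] <- over
  pt <- p$particles
  if (any(pt$radius <= 0) || any(pt$amplitude < 0) || any(pt$amplitude > 1) ||
      any(pt$aspect < 1))
    stop("particle parameters must be physical (radius > 0, 0 <= |t| <= 1)",
         call. = FALSE)
  if (any(pt$kind == "satellite" & 2 * pt$radius >= p$probe_diameter))
    stop("satellites must be smaller than the beam: 2*radius < probe diameter",
         call. = FALSE)
  if ((p$grid_n - 1L) * p$step + p$window > p$object_size)
    stop("scan area plus window exceeds the object", call. = FALSE)

  object <- matrix(complex(real = 1), p$object_size, p$object_size)
  supports <- vector("list", nrow(pt))
  for (i in seq_len(nrow(pt))) {
    idx <- .ellipse_indices(p$object_size, pt$cy[i], pt$cx[i], pt$radius[i],
                            pt$aspect[i], pt$theta[i])
    supports[[i]] <- idx
    object[idx] <- object[idx] * complex(modulus = pt$amplitude[i],
                                         argument = pt$phase[i])
  }
  ctr <- (p$window - 1) / 2
  probe <- matrix(0+0i, p$window, p$window)
  probe[.disk_indices(p$window, ctr, ctr, p$probe_diameter / 2)] <- 1+0i

  pos <- expand.grid(x = (seq_len(p$grid_n) - 1L) * p$step,
                     y = (seq_len(p$grid_n) - 1L) * p$step)
  grid <- build_grid(pos)
  offsets <- cbind(oy = (grid$position_of[, "row"] - 1L) * p$step,
                   ox = (grid$position_of[, "col"] - 1L) * p$step)
  structure(
    c(list(object = object, probe = probe, grid = grid, offsets = offsets,
           supports = supports, preset = preset, seed = as.integer(seed)), p),
    class = "SyntheticScene")
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat(sprintf(
    "<SyntheticScene> '%s': %d x %d object, %d particle(s), %d x %d scan\n",
    x$preset, nrow(x$object), ncol(x$object), nrow(x$particles),
    x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

#' Ground-truth RoI for a synthetic scene
#'
#' A scan position is truly within the RoI iff the probe support disk
#' centered there intersects the support (pixel set) of any selected
#' particle; the test is exact for arbitrary particle shapes.
#'
#' @param scene a `SyntheticScene`.
#' @param kinds particle kinds to include (default: all).
#' @return Object of class `GroundTruth`: `roi_true` (logical grid
#'   matrix), `particles` (data frame), `positions` (list of pattern-index
#'   vectors, one per particle), `grid`.
#' @export
ground_truth <- function(scene, kinds = NULL) {
  stopifnot(inherits(scene, "SyntheticScene"))
  keep <- if (is.null(kinds)) seq_len(nrow(scene$particles))
          else which(scene$particles$kind %in% kinds)
  pt <- scene$particles[keep, , drop = FALSE]
  ctr <- (scene$window - 1) / 2
  pc <- cbind(scene$offsets[, "oy"] + ctr, scene$offsets[, "ox"] + ctr)
  n <- scene$object_size
  positions <- lapply(keep, function(i) {
    idx <- scene$supports[[i]] - 1L
    py <- idx %% n; px <- idx %/% n
    which(vapply(seq_len(nrow(pc)), function(k)
      min((py - pc[k, 1L])^2 + (px - pc[k, 2L])^2) <=
        (scene$probe_diameter / 2)^2, logical(1L)))
  })
  roi <- matrix(FALSE, scene$grid$n_rows, scene$grid$n_cols)
  for (ks in positions)
    roi[scene$grid$position_of[ks, , drop = FALSE]] <- TRUE
  structure(list(roi_true = roi, particles = pt, positions = positions,
                 grid = scene$grid),
            class = "GroundTruth")
}

#' Simulate far-field diffraction patterns for a scene
#'
#' Standard ptychographic forward model: at every scan position the exit
#' wave is the probe times the local object window; the clean intensity is
#' the squared modulus of its centered discrete Fourier transform, scaled
#' so the expected total count of a pattern is
#' `photons * sum(|psi|^2) / sum(|probe|^2)` (a free-space position
#' collects exactly `photons` counts); the recorded pattern is an
#' independent Poisson draw per pixel.
#'
#' @param scene a `SyntheticScene`.
#' @param seed RNG seed for the Poisson noise.
#' @return List: `stack` (noisy `DiffractionStack`), `truth`
#'   ([ground_truth()] over all particles), `clean` (noise-free intensity
#'   array), `scene`.
#' @export
simulate_scene <- function(scene, seed = 0L) {
  stopifnot(inherits(scene, "SyntheticScene"))
  K <- scene$grid$K
  w <- scene$window
  clean <- array(0, c(w, w, K))
  scale <- scene$photons / (w * w * sum(Mod(scene$probe)^2))
  # half-integer frequency sampling: the zero-scattering peak falls on the
  # geometric detector center ((w-1)/2, (w-1)/2), the same center the CoM,
  # wedge and mask conventions use (detector alignment, even-sized frames)
  xr <- seq_len(w) - 1L
  ramp <- exp(-1i * pi * outer(xr, xr, `+`) / w)
  for (k in seq_len(K)) {
    oy <- scene$offsets[k, "oy"]; ox <- scene$offsets[k, "ox"]
    psi <- scene$probe * scene$object[oy + seq_len(w), ox + seq_len(w)]
    clean[, , k] <- .fftshift2(Mod(stats::fft(psi * ramp))^2) * scale
  }
  set.seed(as.integer(seed))
  noisy <- array(as.double(stats::rpois(length(clean), clean)), dim(clean))
  list(stack = diffraction_stack(noisy), truth = ground_truth(scene),
       clean = clean, scene = scene)
}

#' Signal-to-noise ratio of a simulated stack
#'
#' Defined here as the per-pattern ratio of the mean clean intensity to
#' the root-mean-square deviation of the noisy pattern from the clean one,
#' averaged over patterns. For pure Poisson noise on a constant intensity
#' `lambda` this converges to `sqrt(lambda)`. A noise-free stack reports
#' `Inf`.
#'
#' @param noisy a `DiffractionStack` or numeric array, same shape as
#'   `clean`.
#' @param clean noise-free intensity array.
#' @return Scalar SNR.
#' @export
estimate_snr <- function(noisy, clean) {
  if (inherits(noisy, "DiffractionStack")) noisy <- noisy$patterns
  if (!identical(dim(noisy), dim(clean)))
    stop("noisy and clean shapes differ", call. = FALSE)
  if (all(clean == 0)) stop("SNR undefined: clean intensities all zero",
                            call. = FALSE)
  K <- dim(clean)[3L]
  per <- vapply(seq_len(K), function(k) {
    rms <- sqrt(mean((noisy[, , k] - clean[, , k])^2))
    if (rms == 0) Inf else mean(clean[, , k]) / rms
  }, numeric(1L))
  mean(per)
}

#' Score a predicted RoI against ground truth
#'
#' Standard confusion counts over occupied grid cells, plus a per-particle
#' detection flag: a particle counts as detected iff at least one
#' ground-truth scan position overlapping it is predicted.
#'
#' @param pred an `RoIMask`.
#' @param truth a `GroundTruth` on the same grid.
#' @return List: `precision` (0, flagged, when nothing is predicted),
#'   `recall`, `f1`, `tp`, `fp`, `fn`, `detected` (logical per particle,
#'   named by kind), `no_prediction`.
#' @export
score_roi <- function(pred, truth) {
  stopifnot(inherits(pred, "RoIMask"), inherits(truth, "GroundTruth"))
  if (!identical(dim(pred$selected), dim(truth$roi_true)))
    stop("prediction and truth grids differ", call. = FALSE)
  occ <- !is.na(truth$grid$index_of)
  p <- pred$selected & occ
  t <- truth$roi_true & occ
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  no_pred <- (tp + fp) == 0L
  precision <- if (no_pred) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  pred_k <- truth$grid$index_of[p]
  detected <- vapply(truth$positions,
                     function(ks) any(ks %in% pred_k), logical(1L))
  names(detected) <- truth$particles$kind
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, detected = detected,
       no_prediction = no_pred)
}
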