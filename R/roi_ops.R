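# Shift a logical matrix by (dr, dc), padding with `fill`.
.shift_pad <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok], drop = FALSE]
  out
}

.dilate_axis <- function(sel, n, axis) {
  out <- sel
  for (d in seq_len(n)) {
    dr <- if (axis == "y") d else 0L
    dc <- if (axis == "x") d else 0L
    out <- out | .shift_pad(sel, dr, dc) | .shift_pad(sel, -dr, -dc)
  }
  out
}

# erosion pads with TRUE: a missing neighborhood beyond the grid edge never
# counts against a foreground cell (keeps closing extensive)
.erode_axis <- function(sel, n, axis) {
  out <- sel
  for (d in seq_len(n)) {
    dr <- if (axis == "y") d else 0L
    dc <- if (axis == "x") d else 0L
    out <- out & .shift_pad(sel, dr, dc, fill = TRUE) &
      .shift_pad(sel, -dr, -dc, fill = TRUE)
  }
  out
}

#' Grow or shrink an RoI mask by scan steps ("border size")
#'
#' Adjusts the RoI border: a positive step count dilates the mask outwards
#' by that many scan steps along the axis, a negative count erodes it
#' inwards — equivalently, morphology with a rectangular
#' `(2|by|+1) x (2|bx|+1)` structuring element when both signs agree.
#' Outside the grid counts as background for dilation (no wrap-around) but
#' never counts against a foreground cell during erosion, so
#' dilation-then-erosion (closing) always contains the input. Cells added
#' by dilation get provenance tag `"border"`; EMPTY grid cells (no pattern
#' recorded there) are never selected.
#'
#' @param mask an `RoIMask`.
#' @param bx,by signed step counts along x (columns) and y (rows).
#' @param grid optional `ScanGrid` supplying the EMPTY-cell layout.
#' @return The adjusted `RoIMask`.
#' @export
adjust_border <- function(mask, bx = 0L, by = 0L, grid = NULL) {
  stopifnot(inherits(mask, "RoIMask"))
  bx <- as.integer(bx); by <- as.integer(by)
  nr <- nrow(mask$selected); nc <- ncol(mask$selected)
  if (abs(bx) >= nc || abs(by) >= nr)
    stop("border size must be smaller than the grid", call. = FALSE)
  sel <- mask$selected
  if (bx > 0L) sel <- .dilate_axis(sel, bx, "x")
  if (bx < 0L) sel <- .erode_axis(sel, -bx, "x")
  if (by > 0L) sel <- .dilate_axis(sel, by, "y")
  if (by < 0L) sel <- .erode_axis(sel, -by, "y")
  if (!is.null(grid)) sel <- sel & !is.na(grid$index_of)
  prov <- empty_provenance(nr, nc)
  keep <- sel & mask$selected
  prov[keep] <- mask$provenance[keep]
  added <- sel & !mask$selected
  prov[added] <- list("border")
  roi_mask(sel, prov, config = c(mask$config, list(border = c(bx, by))))
}

#' Fill enclosed holes in an RoI mask
#'
#' Background cells 4-connected to the grid boundary stay background; all
#' enclosed background cells become selected with provenance `"fill"`.
#' Useful when only the object's boundary scatters (weakly absorbing
#' objects): the scattering channel outlines the object and the fill-in
#' recovers its interior for reconstruction.
#'
#' @param mask an `RoIMask`.
#' @param grid optional `ScanGrid`; its EMPTY cells conduct the background
#'   flood but are never selected.
#' @return The filled `RoIMask`.
#' @export
fill_in <- function(mask, grid = NULL) {
  stopifnot(inherits(mask, "RoIMask"))
  sel <- mask$selected
  nr <- nrow(sel); nc <- ncol(sel)
  bg <- !sel
  on_boundary <- matrix(FALSE, nr, nc)
  on_boundary[c(1L, nr), ] <- TRUE
  on_boundary[, c(1L, nc)] <- TRUE
  reach <- bg & on_boundary
  repeat {
    grown <- reach |
      (bg & (.shift_pad(reach, 1L, 0L) | .shift_pad(reach, -1L, 0L) |
             .shift_pad(reach, 0L, 1L) | .shift_pad(reach, 0L, -1L)))
    if (identical(grown, reach)) break
    reach <- grown
  }
  holes <- bg & !reach
  if (!is.null(grid)) holes <- holes & !is.na(grid$index_of)
  prov <- mask$provenance
  prov[holes] <- list("fill")
  roi_mask(sel | holes, prov, config = mask$config)
}

#' Percentage of the dataset retained by an RoI
#'
#' @param mask an `RoIMask`.
#' @param grid the matching `ScanGrid` (its `K` is the dataset size).
#' @return Percentage of patterns selected, reported to 0.1%.
#' @examples
#' # 3260 of 15,980 patterns -> 20.4%
#' @export
retained_fraction <- function(mask, grid) {
  stopifnot(inherits(mask, "RoIMask"), inherits(grid, "ScanGrid"))
  if (!identical(dim(mask$selected), dim(grid$index_of)))
    stop("mask dimensions do not match grid", call. = FALSE)
  occ <- !is.na(grid$index_of)
  round(100 * sum(mask$selected & occ) / grid$K, 1L)
}
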