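#' Cell geometry container
#'
#' Bundles the pixel-resolved compartment masks of a single cell together with
#' the bleach region of interest. Rasters are logical matrices indexed
#' `[row, col]`; geometric computations use 0-based pixel-center coordinates
#' with `x = col - 1`, `y = row - 1`.
#'
#' Invariants enforced: the nucleoli mask is a subset of the nucleus mask, the
#' nucleus and cytoplasm masks are disjoint, and the bleach ROI lies entirely
#' inside exactly one compartment (nucleus minus nucleoli, or cytoplasm).
#'
#' @param pixel_size Pixel edge length in micrometres.
#' @param nucleus_mask,nucleoli_mask,cytoplasm_mask Logical matrices of equal
#'   dimension. `nucleoli_mask` may be all-`FALSE`.
#' @param bleach_roi Logical matrix marking the bleached region.
#' @param bleach_center Optional `c(x, y)` 0-based pixel coordinates of the
#'   bleach mid-point; defaults to the centroid of `bleach_roi`.
#' @return An object of class `CellGeometry`.
#' @export
cell_geometry <- function(pixel_size, nucleus_mask, nucleoli_mask = NULL,
                          cytoplasm_mask, bleach_roi, bleach_center = NULL) {
  nucleus_mask <- as.matrix(nucleus_mask) > 0
  cytoplasm_mask <- as.matrix(cytoplasm_mask) > 0
  if (is.null(nucleoli_mask)) {
    nucleoli_mask <- array(FALSE, dim(nucleus_mask))
  } else {
    nucleoli_mask <- as.matrix(nucleoli_mask) > 0
  }
  bleach_roi <- as.matrix(bleach_roi) > 0
  dims <- list(nucleus_mask, nucleoli_mask, cytoplasm_mask, bleach_roi)
  if (length(unique(lapply(dims, dim))) != 1L)
    stop("all masks must share the same dimensions")
  if (any(nucleoli_mask & !nucleus_mask))
    stop("nucleoli mask must be a subset of the nucleus mask")
  if (any(nucleus_mask & cytoplasm_mask))
    stop("nucleus and cytoplasm masks must be disjoint")
  if (!any(bleach_roi))
    stop("bleach ROI is empty")
  in_nuc <- all(nucleus_mask[bleach_roi] & !nucleoli_mask[bleach_roi])
  in_cyt <- all(cytoplasm_mask[bleach_roi])
  if (!xor(in_nuc, in_cyt))
    stop("bleach ROI must lie entirely inside exactly one compartment")
  if (is.null(bleach_center)) {
    co <- pixel_coords(dim(bleach_roi))
    bleach_center <- c(mean(co$x[bleach_roi]), mean(co$y[bleach_roi]))
  }
  structure(
    list(
      pixel_size = pixel_size,
      nucleus_mask = nucleus_mask,
      nucleoli_mask = nucleoli_mask,
      cytoplasm_mask = cytoplasm_mask,
      bleach_roi = bleach_roi,
      bleach_center = bleach_center,
      bleach_compartment = if (in_nuc) "nucleus" else "cytoplasm",
      frame_shape = dim(nucleus_mask)
    ),
    class = "CellGeometry"
  )
}

#' @export
print.CellGeometry <- function(x, ...) {
  cat(sprintf(
    "CellGeometry %dx%d px (%.3f um/px)\n  nucleus %.1f um^2, nucleoli %.1f um^2, cytoplasm %.1f um^2\n  bleach ROI %.1f um^2 in %s at (%.1f, %.1f)\n",
    x$frame_shape[1], x$frame_shape[2], x$pixel_size,
    sum(x$nucleus_mask) * x$pixel_size^2,
    sum(x$nucleoli_mask) * x$pixel_size^2,
    sum(x$cytoplasm_mask) * x$pixel_size^2,
    sum(x$bleach_roi) * x$pixel_size^2,
    x$bleach_compartment, x$bleach_center[1], x$bleach_center[2]
  ))
  invisible(x)
}

## nucleus minus nucleoli: the mask over which nuclear intensities are read
analysis_nucleus_mask <- function(geometry) {
  geometry$nucleus_mask & !geometry$nucleoli_mask
}

## measured shape statistics of a mask (area um^2, eccentricity via moments)
mask_shape_stats <- function(mask, pixel_size = 1) {
  co <- pixel_coords(dim(mask))
  x <- co$x[mask]; y <- co$y[mask]
  n <- length(x)
  if (n == 0L) stop("empty mask")
  mx <- mean(x); my <- mean(y)
  ## second central moments (+ 1/12 per-pixel term, as for regionprops)
  uxx <- mean((x - mx)^2) + 1 / 12
  uyy <- mean((y - my)^2) + 1 / 12
  uxy <- mean((x - mx) * (y - my))
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  list(
    area = n * pixel_size^2,
    centroid = c(mx, my),
    eccentricity = sqrt(max(0, 1 - l2 / l1)),
    major_axis = 4 * sqrt(l1) * pixel_size,
    minor_axis = 4 * sqrt(l2) * pixel_size
  )
}
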