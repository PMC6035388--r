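#' Normalize a raw FRAP intensity series
#'
#' Implements the acquisition normalization convention for recovery curves:
#' the background is subtracted from the bleached-ROI series, the result is
#' divided by the (background-corrected) whole-field trajectory to cancel
#' acquisition photobleaching, and finally by the mean of the prebleach
#' samples so the prebleach level is 1.
#'
#' @param times Acquisition times in seconds (uniform grid).
#' @param raw_roi Intensity series of the bleached ROI.
#' @param background_roi Background intensity series (scalar recycled).
#' @param whole_field Whole-field intensity series tracking acquisition decay.
#' @param is_prebleach Logical flag per sample (metadata, not inferred).
#' @param report_roi Optional reporting-ROI series, normalized the same way
#'   and attached as attribute `report`.
#' @param bleach_duration,roi_area Metadata passed to [recovery_curve()].
#' @return A [recovery_curve()]. Attribute `n_clipped` counts negative
#'   post-subtraction intensities clipped to zero.
#' @export
normalize_frap_curve <- function(times, raw_roi, background_roi, whole_field,
                                 is_prebleach, report_roi = NULL,
                                 bleach_duration = 2.9, roi_area = NA_real_) {
  n <- length(times)
  background_roi <- rep_len(background_roi, n)
  stopifnot(length(raw_roi) == n, length(whole_field) == n,
            length(is_prebleach) == n)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
    stop("non-uniform time grid")

  norm_one <- function(series) {
    s <- series - background_roi
    n_clip <- sum(s < 0)
    if (n_clip > 0) {
      warning(sprintf("%d negative post-subtraction intensities clipped to 0", n_clip))
      s[s < 0] <- 0
    }
    wf <- whole_field - background_roi
    if (any(wf <= 0)) stop("whole-field signal does not exceed background")
    wf <- wf / mean(wf[is_prebleach])
    s <- s / wf
    f_pre <- mean(s[is_prebleach])
    if (f_pre <= 0) stop("prebleach intensity is zero after correction")
    list(values = s / f_pre, n_clipped = n_clip)
  }

  main <- norm_one(raw_roi)
  curve <- recovery_curve(times, main$values, is_prebleach,
                          bleach_duration = bleach_duration,
                          roi_area = roi_area)
  attr(curve, "n_clipped") <- main$n_clipped
  if (!is.null(report_roi)) attr(curve, "report") <- norm_one(report_roi)$values
  curve
}

#' Normalize a FLIP movie against control-cell ROIs
#'
#' Subtracts the background from every frame and divides each frame by the
#' mean of the two control-ROI intensities at that frame (control ROIs are
#' read from an unbleached cell and correct for acquisition bleaching).
#'
#' @param movie A [flip_movie()].
#' @param control_nuc,control_cyt Per-frame control-ROI intensity series.
#' @param background Per-frame background intensity (scalar recycled).
#' @return The normalized [flip_movie()] with `control_normalization` set.
#' @export
normalize_flip_movie <- function(movie, control_nuc, control_cyt, background = 0) {
  nt <- dim(movie$frames)[3L]
  control_nuc <- rep_len(control_nuc, nt)
  control_cyt <- rep_len(control_cyt, nt)
  background <- rep_len(background, nt)
  if (any(control_nuc <= background) || any(control_cyt <= background))
    stop(sprintf("control ROI intensity at or below background at frame %d",
                 which(control_nuc <= background | control_cyt <= background)[1]))
  ctrl <- (control_nuc + control_cyt) / 2
  frames <- movie$frames
  for (k in seq_len(nt)) frames[, , k] <- (frames[, , k] - background[k]) / ctrl[k]
  out <- flip_movie(pmax(frames, 0), frame_interval = movie$frame_interval,
                    bleach_schedule = movie$bleach_schedule,
                    bit_depth = movie$bit_depth,
                    control_normalization = ctrl)
  out
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Places one square ROI in the nucleus and one in the cytoplasm (placement is
#' supplied, not inferred; both should sit at equal distance from the nuclear
#' boundary and avoid nucleoli), subtracts the background from each mean ROI
#' intensity, and returns nuclear over cytoplasmic.
#'
#' @param frame Intensity matrix.
#' @param geometry A [cell_geometry()]; ROIs are checked to lie inside their
#'   compartments.
#' @param nuclear_center,cyto_center `c(x, y)` 0-based centers of the two ROIs.
#' @param roi_side ROI side length in pixels (default 8).
#' @param background Scalar background intensity.
#' @param log2 Return `log2` of the ratio (the plotting convention for
#'   localization time courses).
#' @return The (optionally log2) nuclear-to-cytoplasmic ratio.
#' @export
nc_ratio <- function(frame, geometry, nuclear_center, cyto_center,
                     roi_side = 8, background = 0, log2 = FALSE) {
  roi_mean <- function(center, mask, what) {
    half <- roi_side / 2
    rows <- floor(center[2] - half + 1):ceiling(center[2] + half)
    cols <- floor(center[1] - half + 1):ceiling(center[1] + half)
    rows <- rows[rows >= 1 & rows <= nrow(frame)][seq_len(roi_side)]
    cols <- cols[cols >= 1 & cols <= ncol(frame)][seq_len(roi_side)]
    if (anyNA(rows) || anyNA(cols)) stop(what, " ROI falls outside the frame")
    if (!all(mask[rows, cols])) stop(what, " ROI is not fully inside its compartment")
    mean(frame[rows, cols])
  }
  nuc <- roi_mean(nuclear_center, analysis_nucleus_mask(geometry), "nuclear")
  cyt <- roi_mean(cyto_center, geometry$cytoplasm_mask, "cytoplasmic")
  den <- cyt - background
  if (den <= 0) stop("cytoplasmic ROI intensity does not exceed background")
  r <- (nuc - background) / den
  if (log2) base::log2(r) else r
}
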