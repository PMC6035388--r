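#' FRAP recovery curve
#'
#' A normalized fluorescence recovery time series on a uniform time grid, with
#' prebleach samples flagged by metadata (never inferred from the values).
#' Postbleach times are stored relative to the end of the bleach, so the first
#' postbleach sample sits at `t = 0`.
#'
#' @param times Acquisition times in seconds (uniform grid; prebleach samples
#'   carry negative times).
#' @param intensity Normalized fluorescence (prebleach mean approximately 1).
#' @param is_prebleach Logical flag per sample.
#' @param bleach_duration Bleach duration in seconds.
#' @param roi_area Bleach ROI area in square micrometres.
#' @param steady_state_fraction Fraction of the trailing postbleach samples
#'   averaged to estimate the steady-state intensity `f_oo` (default 0.1).
#' @param validate Check invariants (at least 3 prebleach samples, finite
#'   non-negative intensities, prebleach mean within 5 percent of 1). A curve
#'   that is not yet normalized can be built with `validate = FALSE`.
#' @return A `RecoveryCurve`: a data frame with columns `time_s`, `intensity`,
#'   `is_prebleach` and attributes `f_i` (prebleach mean), `f_oo` (steady
#'   state), `S0` (first postbleach value), `bleach_duration`, `roi_area`.
#' @export
recovery_curve <- function(times, intensity, is_prebleach,
                           bleach_duration = 2.9, roi_area = NA_real_,
                           steady_state_fraction = 0.1, validate = TRUE) {
  stopifnot(length(times) == length(intensity),
            length(times) == length(is_prebleach))
  is_prebleach <- as.logical(is_prebleach)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  post <- !is_prebleach
  if (!any(post)) stop("curve has no postbleach samples")
  f_i <- if (any(is_prebleach)) mean(intensity[is_prebleach]) else NA_real_
  ipost <- intensity[post]
  n_tail <- max(1L, ceiling(steady_state_fraction * sum(post)))
  f_oo <- mean(ipost[(sum(post) - n_tail + 1L):sum(post)])
  if (validate) {
    if (sum(is_prebleach) < 3L)
      warning("fewer than 3 prebleach samples")
    if (any(!is.finite(intensity)) || any(intensity < 0))
      stop("intensities must be finite and non-negative")
    if (!is.na(f_i) && abs(f_i - 1) > 0.05)
      warning(sprintf("prebleach mean %.3f deviates from 1 by more than 5%%", f_i))
  }
  out <- data.frame(time_s = times, intensity = intensity,
                    is_prebleach = is_prebleach)
  structure(out,
            f_i = f_i, f_oo = f_oo, S0 = ipost[1L],
            bleach_duration = bleach_duration, roi_area = roi_area,
            class = c("RecoveryCurve", "data.frame"))
}

## postbleach portion of a curve, times shifted so the first postbleach
## sample is t = 0
postbleach_part <- function(curve) {
  post <- !curve$is_prebleach
  t <- curve$time_s[post]
  list(t = t - t[1L], S = curve$intensity[post])
}

#' @export
print.RecoveryCurve <- function(x, ...) {
  cat(sprintf(
    "RecoveryCurve: %d samples (%d prebleach), f_i=%.3f, S0=%.3f, f_oo=%.3f\n",
    nrow(x), sum(x$is_prebleach), attr(x, "f_i"), attr(x, "S0"), attr(x, "f_oo")))
  invisible(x)
}

#' FLIP movie container
#'
#' @param frames Numeric array `[row, col, frame]` of intensities.
#' @param frame_interval Time between consecutive frames in seconds.
#' @param bleach_schedule Per-frame bleach duration in seconds (length equal to
#'   the number of frames; the bleach happens in the interval following each
#'   frame). A scalar is recycled.
#' @param bit_depth Acquisition bit depth (metadata; 12 for the default
#'   protocol).
#' @param control_normalization Optional per-frame scalar recording the
#'   control-ROI normalization already applied.
#' @return A `FlipMovie` object.
#' @export
flip_movie <- function(frames, frame_interval = 2, bleach_schedule = 2,
                       bit_depth = 12, control_normalization = NULL) {
  frames <- as.array(frames)
  if (length(dim(frames)) != 3L) stop("frames must be a [row, col, frame] array")
  nt <- dim(frames)[3L]
  if (nt < 2L) stop("a FLIP movie needs at least 2 frames")
  bleach_schedule <- rep_len(bleach_schedule, nt)
  if (any(bleach_schedule < 0) || any(bleach_schedule > frame_interval))
    stop("per-frame bleach durations must lie in [0, frame_interval]")
  structure(
    list(frames = frames, frame_interval = frame_interval,
         bleach_schedule = bleach_schedule, bit_depth = bit_depth,
         control_normalization = control_normalization),
    class = "FlipMovie")
}

#' @export
print.FlipMovie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("FlipMovie: %dx%d px, %d frames every %.2g s (bleach %.2g s/frame, %d-bit)\n",
              d[1], d[2], d[3], x$frame_interval, x$bleach_schedule[1], x$bit_depth))
  invisible(x)
}

#' Fit result container
#'
#' Uniform record of a model fit: parameter vector with units, the weighted
#' error it minimizes, information-criterion statistics and plausibility flags.
#'
#' @param model_id Model identifier string.
#' @param parameters Named numeric vector.
#' @param units Named character vector matching `parameters`.
#' @param weighted_sse Minimized weighted sum of squares of error.
#' @param aic,akaike_weight Model-selection statistics (filled by
#'   [select_model()]; `NA` until then).
#' @param plausible Logical plausibility flag.
#' @param discarded_reason Reason code when a fit is discarded, else `NA`.
#' @param noisy Logical: optimizer failure / uninterpretable curve.
#' @param extra Free-form list of extras (e.g. forward-model settings).
#' @return A `FitResult` object.
#' @export
fit_result <- function(model_id, parameters, units = NULL,
                       weighted_sse = NA_real_, aic = NA_real_,
                       akaike_weight = NA_real_, plausible = TRUE,
                       discarded_reason = NA_character_, noisy = FALSE,
                       extra = list()) {
  if (!is.na(akaike_weight) && (akaike_weight < 0 || akaike_weight > 1))
    stop("akaike_weight must lie in [0, 1]")
  if (!plausible && is.na(discarded_reason))
    stop("a discarded fit must carry a reason code")
  structure(
    list(model_id = model_id, parameters = parameters, units = units,
         weighted_sse = weighted_sse, aic = aic,
         akaike_weight = akaike_weight, plausible = plausible,
         discarded_reason = discarded_reason, noisy = noisy, extra = extra),
    class = "FitResult")
}

#' @export
print.FitResult <- function(x, ...) {
  cat(sprintf("FitResult [%s] wSSE=%.4g AIC=%.4g w=%.3g %s\n", x$model_id,
              x$weighted_sse, x$aic, x$akaike_weight,
              if (x$plausible) "" else paste0("DISCARDED: ", x$discarded_reason)))
  pp <- format(x$parameters, digits = 4)
  cat(paste0("  ", names(pp), " = ", pp,
             if (!is.null(x$units)) paste0(" ", x$units[names(pp)]) else "",
             collapse = "\n"), "\n")
  invisible(x)
}
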