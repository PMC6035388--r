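#' Read and write recovery curves as CSV
#'
#' Curves are stored as plain CSV with columns `time_s`, `intensity`,
#' `is_prebleach`. Numbers are written with 17 significant digits so a
#' write/read round trip reproduces the doubles bit-exactly.
#'
#' @param curve A [recovery_curve()].
#' @param path File path.
#' @return `read_curve_csv` returns a `RecoveryCurve`.
#' @export
write_curve_csv <- function(curve, path) {
  df <- data.frame(
    time_s = sprintf("%.17g", curve$time_s),
    intensity = sprintf("%.17g", curve$intensity),
    is_prebleach = as.integer(curve$is_prebleach))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param bleach_duration,roi_area Metadata not stored in the CSV.
#' @param ... Passed to [recovery_curve()].
#' @export
read_curve_csv <- function(path, bleach_duration = 2.9, roi_area = NA_real_, ...) {
  df <- utils::read.csv(path)
  recovery_curve(df$time_s, df$intensity, df$is_prebleach == 1,
                 bleach_duration = bleach_duration, roi_area = roi_area, ...)
}

#' Read and write label/binary masks as 8-bit multi-page TIFF
#'
#' Masks and label images with values in 0..255 are stored one page per
#' frame. Values round-trip exactly.
#'
#' @param masks A matrix, or a list of matrices (multi-page), of integer
#'   labels in 0..255.
#' @param path File path.
#' @export
write_mask_tiff <- function(masks, path) {
  if (is.matrix(masks)) masks <- list(masks)
  pages <- lapply(masks, function(m) {
    m <- as.matrix(m) * 1
    if (any(m < 0 | m > 255)) stop("mask labels must lie in 0..255")
    m / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @return `read_mask_tiff` returns a list of integer matrices.
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    m <- round(p * 255)
    storage.mode(m) <- "integer"
    m
  })
}

#' Read and write intensity movies as 16-bit multi-page TIFF
#'
#' Frames are quantized to the movie's acquisition bit depth (values are
#' assumed normalized to `[0, scale]`) and stored as 16-bit TIFF pages, the
#' usual interchange representation for microscopy data. A movie whose values
#' already sit on the quantization lattice round-trips bit-exactly.
#'
#' @param movie A [flip_movie()].
#' @param path File path.
#' @param scale Intensity mapped to the top code value (default: the movie
#'   maximum rounded up, stored in the file is not needed to re-read because
#'   the caller supplies it).
#' @export
write_movie_tiff <- function(movie, path, scale = 1) {
  nt <- dim(movie$frames)[3L]
  top <- 2^movie$bit_depth - 1
  pages <- lapply(seq_len(nt), function(k) {
    m <- movie$frames[, , k] / scale
    m <- pmin(pmax(m, 0), 1)
    round(m * top) / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_interval,bleach_schedule,bit_depth Metadata for the rebuilt
#'   [flip_movie()].
#' @export
read_movie_tiff <- function(path, frame_interval = 2, bleach_schedule = 2,
                            bit_depth = 12, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  top <- 2^bit_depth - 1
  frames <- vapply(pages, function(p) {
    storage.mode(p) <- "double"
    round(p * (2^16 - 1)) / (2^16 - 1) * scale
  }, matrix(0, nrow(pages[[1]]), ncol(pages[[1]])))
  ## snap back onto the acquisition lattice
  frames <- round(frames * top) / top * scale
  flip_movie(frames, frame_interval = frame_interval,
             bleach_schedule = bleach_schedule, bit_depth = bit_depth)
}

#' Read and write fit results as JSON
#'
#' @param fit A [fit_result()].
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model_id = fit$model_id,
         parameters = as.list(fit$parameters),
         units = as.list(fit$units %||% character()),
         weighted_sse = fit$weighted_sse, aic = fit$aic,
         akaike_weight = fit$akaike_weight, plausible = fit$plausible,
         discarded_reason = fit$discarded_reason, noisy = fit$noisy),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_result(model_id = x$model_id,
             parameters = unlist(x$parameters),
             units = if (length(x$units)) unlist(x$units) else NULL,
             weighted_sse = x$weighted_sse %||% NA_real_,
             aic = x$aic %||% NA_real_,
             akaike_weight = x$akaike_weight %||% NA_real_,
             plausible = x$plausible %||% TRUE,
             discarded_reason = x$discarded_reason %||% NA_character_,
             noisy = x$noisy %||% FALSE)
}

#' Read and write configuration as YAML
#'
#' Configuration carries pixel sizes, frame intervals, ROI geometry, solver
#' tolerances and seeds.
#'
#' @param config Named list.
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) yaml::read_yaml(path)

#' Default analysis configuration
#'
#' Pixel sizes are back-calculated from the stated ROI areas: an 8x8 px FLIP
#' square of about 4.46 um^2 gives 0.264 um/px, an 11 px diameter FRAP circle
#' of about 3.1 um^2 gives 0.181 um/px.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    pixel_size_flip = 0.264,
    pixel_size_frap = 0.181,
    frap = list(frame_interval = 0.06, bleach_duration = 2.9,
                t_max = 18, n_prebleach = 3),
    flip = list(frame_interval = 2, bleach_duration = 2, n_frames = 150,
                roi_side_px = 8, bit_depth = 12),
    solver = list(rtol = 1e-8, atol = 1e-10),
    noise_sd = 0.02
  )
}
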