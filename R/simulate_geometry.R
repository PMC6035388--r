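#' Geometry specification for the synthetic cell builder
#'
#' @param frame_shape Frame size in pixels `c(rows, cols)`.
#' @param pixel_size Micrometres per pixel.
#' @param nucleus_area Target nuclear area, um^2.
#' @param eccentricity Target nuclear eccentricity in [0, 1).
#' @param n_nucleoli Number of nucleoli discs.
#' @param nucleolus_radius Nucleolus radius, um.
#' @param cyto_ratio Cytoplasm-to-nucleus area ratio target (typically 1-2).
#' @param bleach List describing the bleach ROI: `shape` (`"circle"` or
#'   `"square"`), `radius_px` or `side_px`, `placement` (`"center"` or
#'   `"right_shifted"`), `compartment`.
#' @return A `GeometrySpec` list.
#' @export
geometry_spec <- function(frame_shape = c(128L, 128L), pixel_size = 0.264,
                          nucleus_area = 180, eccentricity = 0.75,
                          n_nucleoli = 2L, nucleolus_radius = 1.2,
                          cyto_ratio = 1.5,
                          bleach = list(shape = "square", side_px = 8L,
                                        placement = "center",
                                        compartment = "nucleus")) {
  structure(list(frame_shape = frame_shape, pixel_size = pixel_size,
                 nucleus_area = nucleus_area, eccentricity = eccentricity,
                 n_nucleoli = n_nucleoli, nucleolus_radius = nucleolus_radius,
                 cyto_ratio = cyto_ratio, bleach = bleach),
            class = "GeometrySpec")
}

#' Build a synthetic cell geometry
#'
#' Deterministically (for a fixed seed) constructs pixel masks for an
#' elliptical nucleus with the requested area and eccentricity, nucleoli
#' discs inside it, and a surrounding cytoplasmic shell scaled so the
#' cytoplasm-to-nucleus area ratio matches the target, emulating manually
#' traced boundaries. The bleach ROI is placed at the nucleus centre or
#' right-shifted toward the nuclear-cytoplasmic boundary; square FLIP ROIs
#' are snapped to the ROI-sized lattice so one grid point overlaps the
#' bleach region exactly.
#'
#' @param spec A [geometry_spec()].
#' @param seed Integer seed (orientation and nucleoli placement).
#' @return A [cell_geometry()].
#' @export
make_geometry <- function(spec = geometry_spec(), seed = 1L) {
  set.seed(seed)
  fs <- spec$frame_shape
  ps <- spec$pixel_size
  co <- pixel_coords(fs)
  cx <- (fs[2] - 1) / 2; cy <- (fs[1] - 1) / 2

  e <- spec$eccentricity
  A_px <- spec$nucleus_area / ps^2
  b <- sqrt(A_px / pi * sqrt(1 - e^2))       # semi-minor, px
  a <- A_px / pi / b                          # semi-major, px
  th <- stats::runif(1, 0, pi)
  s_out <- sqrt(1 + spec$cyto_ratio)
  if (a * s_out > min(cx, cy) * 0.95 || b * s_out > min(cx, cy) * 0.95)
    stop("infeasible geometry: cell does not fit the frame")
  xr <- (co$x - cx) * cos(th) + (co$y - cy) * sin(th)
  yr <- -(co$x - cx) * sin(th) + (co$y - cy) * cos(th)
  rho2 <- (xr / a)^2 + (yr / b)^2
  nucleus <- rho2 <= 1
  cyto <- rho2 <= s_out^2 & !nucleus

  ## bleach ROI first, so nucleoli can be placed clear of it
  bl <- spec$bleach
  shift <- if (identical(bl$placement, "right_shifted")) 0.6 else 0
  bx <- cx + shift * a * cos(th); by <- cy + shift * a * sin(th)
  if (identical(bl$shape, "circle")) {
    roi <- (co$x - bx)^2 + (co$y - by)^2 <= bl$radius_px^2
  } else {
    side <- bl$side_px
    ## snap the ROI corner onto the side-length lattice
    c0 <- round((bx - side / 2) / side) * side
    r0 <- round((by - side / 2) / side) * side
    roi <- co$x >= c0 & co$x < c0 + side & co$y >= r0 & co$y < r0 + side
  }
  target <- if (identical(bl$compartment, "cytoplasm")) cyto else nucleus
  if (!all(target[roi])) stop("infeasible spec: bleach ROI does not fit its compartment")

  nucleoli <- array(FALSE, fs)
  if (spec$n_nucleoli > 0L) {
    rn_px <- spec$nucleolus_radius / ps
    roi_xy <- c(mean(co$x[roi]), mean(co$y[roi]))
    roi_half <- sqrt(sum(roi)) / 2
    for (i in seq_len(spec$n_nucleoli)) {
      placed <- FALSE
      for (try in 1:200) {
        u <- stats::runif(2, -0.55, 0.55)
        ncx <- cx + u[1] * a * cos(th) - u[2] * b * sin(th)
        ncy <- cy + u[1] * a * sin(th) + u[2] * b * cos(th)
        cand <- (co$x - ncx)^2 + (co$y - ncy)^2 <= rn_px^2
        inside <- all(nucleus[cand])
        clear <- sqrt((ncx - roi_xy[1])^2 + (ncy - roi_xy[2])^2) >
          rn_px + roi_half + 2
        if (inside && clear) { nucleoli <- nucleoli | cand; placed <- TRUE; break }
      }
      if (!placed) stop("infeasible spec: could not place nucleoli")
    }
  }

  cell_geometry(pixel_size = ps, nucleus_mask = nucleus,
                nucleoli_mask = nucleoli, cytoplasm_mask = cyto,
                bleach_roi = roi)
}

#' Simulate a first-postbleach frame
#'
#' Pixel values inside the nucleus follow the Gaussian-exponential bleach
#' profile `exp(-K exp(-2 r^2 / r_e^2))` about the bleach centre; pixels
#' outside the nucleus stay at the unbleached level 1; nucleoli are dark.
#' Gaussian noise of standard deviation `noise_sd` is added everywhere.
#'
#' @param K Bleach depth (> 0).
#' @param r_e Effective radius, um (> 0).
#' @param geometry A [cell_geometry()] with a nuclear bleach ROI.
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param seed Integer seed.
#' @return An intensity matrix.
#' @export
simulate_postbleach_profile <- function(K, r_e, geometry, noise_sd = 0,
                                        seed = 1L) {
  stopifnot(K > 0, r_e > 0)
  set.seed(seed)
  co <- pixel_coords(geometry$frame_shape)
  ctr <- geometry$bleach_center
  r_um <- sqrt((co$x - ctr[1])^2 + (co$y - ctr[2])^2) * geometry$pixel_size
  frame <- array(1, geometry$frame_shape)
  nuc <- analysis_nucleus_mask(geometry)
  frame[nuc] <- profile_model(r_um[nuc], K, r_e)
  frame[geometry$nucleoli_mask] <- 0.05
  if (noise_sd > 0)
    frame <- frame + stats::rnorm(length(frame), 0, noise_sd)
  frame
}
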