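#' FLIP acquisition protocol
#'
#' Default: 150 frames every 2 s, the 8x8 px square ROI bleached for 2 s
#' between consecutive frames (with a 2 s frame interval this duty cycle
#' keeps the sink on continuously; shorter bleach durations interleave sink
#' and free evolution).
#'
#' @param frame_interval Seconds between frames.
#' @param n_frames Number of frames.
#' @param bleach_duration Bleach seconds after each frame.
#' @param mode `"interleaved"` applies the sink only during the bleach
#'   window after each frame; `"continuous"` keeps it on for the whole
#'   interval regardless of `bleach_duration`.
#' @return A protocol list.
#' @export
flip_protocol <- function(frame_interval = 2, n_frames = 150L,
                          bleach_duration = 2,
                          mode = c("interleaved", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(bleach_duration <= frame_interval)
  list(frame_interval = frame_interval, n_frames = n_frames,
       bleach_duration = if (mode == "continuous") frame_interval
       else bleach_duration,
       mode = mode)
}

#' Simulate a FLIP movie from known ground truth
#'
#' Solves the compartmentalized loss model forward from its prebleach steady
#' state on the coarse grid (optionally refined) and renders the solution
#' onto the pixel raster: each in-mask pixel takes the value of its grid
#' point (pixels falling in unlabelled edge grid points take the value of
#' the nearest labelled grid point of their compartment), which is the
#' piecewise-constant area-weighted sampling of the solution. Gaussian noise
#' is added to every pixel.
#'
#' @param truth A [ground_truth()] (fields `k1`, `km1`, `k2`, `km2`, `eta`,
#'   `C0`, `D`, `noise_sd`, `seed`).
#' @param geometry A [cell_geometry()] with a lattice-aligned square bleach
#'   ROI in the nucleus.
#' @param protocol A [flip_protocol()].
#' @param refine Grid refinement for the forward solve.
#' @return A [flip_movie()] with attributes `truth`, `solution`.
#' @export
simulate_flip_movie <- function(truth, geometry, protocol = flip_protocol(),
                                refine = 1L) {
  params <- flip_parameters(k1 = truth$k1, k2 = truth$k2, km2 = truth$km2,
                            eta = truth$eta, C0 = truth$C0, D = truth$D,
                            km1 = truth$km1)
  grid <- discretize(geometry, refine = refine)
  sol <- solve_flip_forward(params, grid, n_frames = protocol$n_frames,
                            frame_interval = protocol$frame_interval,
                            bleach_duration = protocol$bleach_duration)
  fs <- geometry$frame_shape
  nt <- protocol$n_frames
  frames <- array(0, c(fs, nt))
  idx <- grid$index
  ## per labelled cell: paint its in-mask pixels
  painted <- array(FALSE, fs)
  for (i in seq_along(idx$cells)) {
    px <- grid$cell_pixels[[i]]
    if (is.null(px) || nrow(px) == 0L) next
    lin <- (px[, 2] - 1L) * fs[1] + px[, 1]
    for (k in seq_len(nt)) frames[lin + (k - 1L) * prod(fs)] <- sol$G[i, k]
    painted[lin] <- TRUE
  }
  ## in-mask pixels of unlabelled grid points: nearest labelled cell of the
  ## same compartment
  nuc <- analysis_nucleus_mask(geometry); cyt <- geometry$cytoplasm_mask
  left <- which((nuc | cyt) & !painted, arr.ind = TRUE)
  if (nrow(left) > 0L) {
    centers <- cbind(grid$offset[1] + (idx$gr - 0.5) * grid$h_px,
                     grid$offset[2] + (idx$gc - 0.5) * grid$h_px)
    for (m in seq_len(nrow(left))) {
      p <- left[m, ]
      want_nuc <- nuc[p[1], p[2]]
      cand <- which(idx$nuclear == want_nuc)
      d2 <- (centers[cand, 1] - p[1])^2 + (centers[cand, 2] - p[2])^2
      i <- cand[which.min(d2)]
      frames[p[1], p[2], ] <- sol$G[i, ]
    }
  }
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    frames <- frames + array(stats::rnorm(length(frames), 0, truth$noise_sd),
                             dim(frames))
    frames[frames < 0] <- 0
  }
  movie <- flip_movie(frames, frame_interval = protocol$frame_interval,
                      bleach_schedule = protocol$bleach_duration,
                      bit_depth = 12)
  attr(movie, "truth") <- truth
  attr(movie, "solution") <- sol
  movie
}
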