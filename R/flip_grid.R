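#' Discretize a cell onto the coarse FLIP grid
#'
#' Divides the frame into square grid points with the same dimensions as the
#' bleach region, with the lattice aligned so one grid point overlaps the
#' bleach ROI exactly. A grid point is labelled nuclear or cytoplasmic when
#' at least half of it is occupied by the corresponding mask (nucleus minus
#' nucleoli for the nuclear label); the bleach grid point is labelled `B`.
#' When a movie is supplied, the intensity of a grid point at each frame is
#' the mean over the pixels of that grid point that overlap its compartment
#' mask.
#'
#' @param geometry A [cell_geometry()] whose bleach ROI is a lattice-aligned
#'   square.
#' @param movie Optional [flip_movie()] to grid.
#' @param refine Integer lattice refinement factor: `refine = 2` halves the
#'   grid spacing (the bleach region then spans several grid points, all
#'   labelled `B`).
#' @param occupancy Minimum mask occupancy for a label (default 0.5).
#' @return A `CompartmentGrid`: list with `labels` (matrix of `""`, `"N"`,
#'   `"C"`, `"B"`), `h_um`, `h_px`, `cell_pixels` (per labelled cell, its
#'   in-mask pixel indices), `index` (labelled-cell bookkeeping) and, when a
#'   movie is given, `S` (cells x frames intensity matrix) and `times`.
#' @export
discretize <- function(geometry, movie = NULL, refine = 1L, occupancy = 0.5) {
  fs <- geometry$frame_shape
  roi <- geometry$bleach_roi
  rows <- range(which(rowSums(roi) > 0)); cols <- range(which(colSums(roi) > 0))
  side <- rows[2] - rows[1] + 1L
  if (side != (cols[2] - cols[1] + 1L) || sum(roi) != side^2)
    stop("bleach ROI must be square for FLIP gridding")
  h_px <- side / refine
  if (h_px != round(h_px)) stop("refinement must divide the ROI side")
  h_px <- as.integer(h_px)
  ## lattice offset so that the ROI corner is on the lattice
  off_r <- (rows[1] - 1L) %% h_px
  off_c <- (cols[1] - 1L) %% h_px
  nuc <- analysis_nucleus_mask(geometry)
  cyt <- geometry$cytoplasm_mask

  n_gr <- (fs[1] - off_r) %/% h_px
  n_gc <- (fs[2] - off_c) %/% h_px
  labels <- matrix("", n_gr, n_gc)
  cell_pixels <- vector("list", n_gr * n_gc)
  for (gi in seq_len(n_gr)) {
    for (gj in seq_len(n_gc)) {
      rr <- (off_r + (gi - 1L) * h_px + 1L):(off_r + gi * h_px)
      cc <- (off_c + (gj - 1L) * h_px + 1L):(off_c + gj * h_px)
      fn <- mean(nuc[rr, cc]); fc <- mean(cyt[rr, cc])
      lab <- ""
      if (fn >= occupancy || fc >= occupancy)
        lab <- if (fn >= fc) "N" else "C"
      if (all(roi[rr, cc])) lab <- "B"
      labels[gi, gj] <- lab
      if (lab != "") {
        m <- if (lab == "C") cyt[rr, cc] else nuc[rr, cc]
        idx <- which(m, arr.ind = TRUE)
        cell_pixels[[(gj - 1L) * n_gr + gi]] <-
          cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
      }
    }
  }
  if (sum(labels == "B") != refine^2)
    stop("bleach ROI could not be aligned to the grid")

  keep <- which(labels != "")
  lab_v <- labels[keep]
  index <- list(cells = keep, labels = lab_v,
                gr = (keep - 1L) %% n_gr + 1L,
                gc = (keep - 1L) %/% n_gr + 1L,
                nuclear = lab_v %in% c("N", "B"),
                bleach = lab_v == "B")
  grid <- structure(
    list(labels = labels, h_um = h_px * geometry$pixel_size, h_px = h_px,
         refine = refine, offset = c(off_r, off_c),
         cell_pixels = cell_pixels[keep], index = index,
         frame_shape = fs),
    class = "CompartmentGrid")
  if (!is.null(movie)) {
    nt <- dim(movie$frames)[3L]
    S <- matrix(0, length(keep), nt)
    for (i in seq_along(keep)) {
      px <- grid$cell_pixels[[i]]
      if (is.null(px) || nrow(px) == 0L) next
      lin <- (px[, 2] - 1L) * fs[1] + px[, 1]
      for (k in seq_len(nt)) S[i, k] <- mean(movie$frames[, , k][lin])
    }
    grid$S <- S
    grid$times <- (seq_len(nt) - 1L) * movie$frame_interval
    grid$bleach_schedule <- movie$bleach_schedule
  }
  grid
}

#' @export
print.CompartmentGrid <- function(x, ...) {
  tb <- table(factor(x$index$labels, levels = c("B", "N", "C")))
  cat(sprintf("CompartmentGrid: %.2f um spacing, %d bleach / %d nuclear / %d cytoplasmic points\n",
              x$h_um, tb["B"], tb["N"], tb["C"]))
  invisible(x)
}
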