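#' Track cells across a label movie
#'
#' Two-stage tracker over paired nuclei/cell channels. Frame processing:
#' objects are labelled, small objects below `area_min` removed, single
#' cytoplasmic objects overlapping several nuclei are split by propagation
#' from the nuclei (handling both touching cells and divisions), objects
#' without a nucleus and objects touching the frame border are removed for
#' that frame. Frame joining: objects are matched to the previous frame by
#' pixel overlap, with one-to-many and many-to-one overlaps resolved by
#' largest overlap; unmatched objects start new identities. Tracks shorter
#' than `min_frames` consecutive frames are dropped.
#'
#' @param nuclei Array `[row, col, frame]` of nucleus masks (binary or
#'   labelled).
#' @param cells Array of the same shape for the cell (cytoplasm+nucleus)
#'   channel.
#' @param intensity Optional intensity array for per-frame N/C ratio
#'   readouts (median nuclear over median cytoplasmic intensity).
#' @param pixel_size Micrometres per pixel.
#' @param min_frames Minimum consecutive frames for a track (default 24,
#'   i.e. two hours at 5-minute frames).
#' @param area_min Minimum object area in pixels.
#' @return List of `Track` data frames (columns `frame`, `x`, `y`,
#'   `area`, `perimeter`, `eccentricity`, `circularity`, `nuc_area`,
#'   `nc_ratio`), named by track id; attribute `label_movie` holds the
#'   relabelled movie.
#' @export
track_cells <- function(nuclei, cells, intensity = NULL, pixel_size = 1,
                        min_frames = 24L, area_min = 20L) {
  if (length(dim(cells)) != 3L) stop("empty or malformed movie")
  nt <- dim(cells)[3L]
  fs <- dim(cells)[1:2]
  out_labels <- array(0L, dim(cells))
  next_id <- 1L
  prev <- NULL
  frame_objects <- vector("list", nt)

  for (k in seq_len(nt)) {
    cell_bin <- cells[, , k] > 0
    nuc_bin <- nuclei[, , k] > 0
    lab <- EBImage::bwlabel(cell_bin)
    nlab <- EBImage::bwlabel(nuc_bin)
    ## area threshold
    tab <- tabulate(lab[lab > 0])
    for (o in which(tab < area_min)) lab[lab == o] <- 0L
    ## split objects overlapping >= 2 nuclei; drop nucleus-less objects
    objs <- setdiff(unique(as.integer(lab)), 0L)
    seg <- matrix(0L, fs[1], fs[2])
    offset <- 0L
    for (o in objs) {
      obj <- lab == o
      nuc_ids <- setdiff(unique(as.integer(nlab[obj])), 0L)
      if (length(nuc_ids) == 0L) next                      # no nucleus
      if (length(nuc_ids) == 1L) {
        seg[obj] <- offset + 1L
        offset <- offset + 1L
      } else {
        seeds <- matrix(0L, fs[1], fs[2])
        for (s in seq_along(nuc_ids)) seeds[nlab == nuc_ids[s] & obj] <- s
        sp <- EBImage::propagate(EBImage::distmap(obj * 1), seeds,
                                 mask = obj)
        sp <- as.integer(round(as.matrix(sp)))
        pieces <- setdiff(unique(sp), 0L)
        for (s in pieces) {
          seg[matrix(sp, fs[1], fs[2]) == s & obj] <- offset + 1L
          offset <- offset + 1L
        }
      }
    }
    ## remove border-touching objects in this frame
    border <- unique(c(seg[1, ], seg[fs[1], ], seg[, 1], seg[, fs[2]]))
    for (o in setdiff(border, 0L)) seg[seg == o] <- 0L

    ## frame joining by overlap with previous relabelled frame
    cur_ids <- setdiff(unique(as.integer(seg)), 0L)
    relab <- matrix(0L, fs[1], fs[2])
    if (length(cur_ids) > 0L) {
      assign_df <- NULL
      for (o in cur_ids) {
        obj <- seg == o
        cand <- if (is.null(prev)) integer(0) else as.integer(prev[obj])
        cand <- cand[cand > 0L]
        if (length(cand) > 0L) {
          tb <- sort(table(cand), decreasing = TRUE)
          assign_df <- rbind(assign_df,
                             data.frame(obj = o, prev_id = as.integer(names(tb)[1]),
                                        overlap = as.integer(tb[1])))
        } else {
          assign_df <- rbind(assign_df,
                             data.frame(obj = o, prev_id = NA_integer_,
                                        overlap = 0L))
        }
      }
      ## many-to-one: largest overlap keeps the previous identity
      assign_df <- assign_df[order(-assign_df$overlap), ]
      taken <- integer(0)
      for (r in seq_len(nrow(assign_df))) {
        pid <- assign_df$prev_id[r]
        if (!is.na(pid) && !(pid %in% taken)) {
          assign_df$final[r] <- pid
          taken <- c(taken, pid)
        } else {
          assign_df$final[r] <- next_id
          next_id <- next_id + 1L
        }
      }
      for (r in seq_len(nrow(assign_df)))
        relab[seg == assign_df$obj[r]] <- assign_df$final[r]
    }
    out_labels[, , k] <- relab
    prev <- relab

    ## record per-object measurements
    ids_here <- setdiff(unique(as.integer(relab)), 0L)
    if (length(ids_here) > 0L) {
      frame_objects[[k]] <- lapply(stats::setNames(ids_here, ids_here), function(id) {
        obj <- relab == id
        m <- morphology(obj, pixel_size)
        nuc_obj <- nuc_bin & obj
        nc <- NA_real_
        if (!is.null(intensity) && any(nuc_obj) && any(obj & !nuc_obj)) {
          fr <- intensity[, , k]
          den <- stats::median(fr[obj & !nuc_obj])
          if (den > 0) nc <- stats::median(fr[nuc_obj]) / den
        }
        data.frame(frame = k, x = m$centroid[1], y = m$centroid[2],
                   area = m$area, perimeter = m$perimeter,
                   eccentricity = m$eccentricity,
                   circularity = m$circularity,
                   nuc_area = sum(nuc_obj) * pixel_size^2,
                   nc_ratio = nc)
      })
    }
  }

  ## assemble per-id tracks, keep longest consecutive run, drop short tracks
  all_ids <- sort(unique(unlist(lapply(frame_objects, names))))
  tracks <- list()
  for (id in all_ids) {
    rows <- do.call(rbind, lapply(frame_objects, function(fo) fo[[id]]))
    if (is.null(rows)) next
    runs <- split(rows, cumsum(c(1, diff(rows$frame) != 1)))
    best <- runs[[which.max(vapply(runs, nrow, 0L))]]
    if (nrow(best) >= min_frames) tracks[[id]] <- best
  }
  structure(tracks, label_movie = out_labels, class = "TrackSet")
}

#' Simulate a label movie with known tracks
#'
#' Cells are ellipses with a nuclear disc, moving by a seeded random walk
#' (or along supplied paths); supports touching cells, frame-border exits
#' and a division event (the nucleus splits into two, then the daughters
#' separate). Returns the two label channels plus the ground-truth table.
#'
#' @param n_cells Number of cells.
#' @param n_frames Number of frames.
#' @param frame_shape `c(rows, cols)`.
#' @param step_sd Random-walk step standard deviation, px/frame.
#' @param cell_radius,nuc_radius Cell and nucleus radii, px.
#' @param paths Optional list of `n_frames x 2` center matrices (overrides
#'   the random walk; `NA` rows mean the cell is absent).
#' @param division Optional list `list(cell = i, frame = f, offset = d)`:
#'   cell `i` divides at frame `f`, daughters drifting apart by `d` px per
#'   frame along x.
#' @param seed Integer seed.
#' @return List with `nuclei`, `cells` (label arrays) and `truth` (data
#'   frame `frame`, `id`, `x`, `y`, `present`).
#' @export
simulate_tracking_movie <- function(n_cells = 3L, n_frames = 30L,
                                    frame_shape = c(128L, 128L),
                                    step_sd = 1.5, cell_radius = 14,
                                    nuc_radius = 6, paths = NULL,
                                    division = NULL, seed = 1L) {
  stopifnot(n_cells >= 1L)
  set.seed(seed)
  fs <- frame_shape
  if (is.null(paths)) {
    paths <- lapply(seq_len(n_cells), function(i) {
      start <- c(stats::runif(1, cell_radius + 2, fs[2] - cell_radius - 2),
                 stats::runif(1, cell_radius + 2, fs[1] - cell_radius - 2))
      steps <- matrix(stats::rnorm(2 * n_frames, 0, step_sd), n_frames, 2)
      steps[1, ] <- 0
      p <- sweep(apply(steps, 2, cumsum), 2, start, "+")
      p
    })
  }
  co <- pixel_coords(fs)
  nuclei <- array(0L, c(fs, n_frames))
  cells <- array(0L, c(fs, n_frames))
  truth <- NULL
  div_id <- n_cells + 1L
  for (k in seq_len(n_frames)) {
    for (i in seq_len(n_cells)) {
      ctr <- paths[[i]][k, ]
      if (anyNA(ctr)) next
      dividing <- !is.null(division) && division$cell == i && k >= division$frame
      centers <- if (dividing) {
        drift <- division$offset * (k - division$frame + 1L)
        list(c(ctr[1] - drift, ctr[2]), c(ctr[1] + drift, ctr[2]))
      } else list(ctr)
      ids <- if (dividing) c(i, div_id) else i
      for (j in seq_along(centers)) {
        cc <- centers[[j]]
        cell_px <- (co$x - cc[1])^2 + (co$y - cc[2])^2 <= cell_radius^2
        nuc_px <- (co$x - cc[1])^2 + (co$y - cc[2])^2 <= nuc_radius^2
        cells[, , k][cell_px] <- ids[j]
        nuclei[, , k][nuc_px] <- ids[j]
        present <- any(cell_px)
        truth <- rbind(truth, data.frame(frame = k, id = ids[j],
                                         x = cc[1], y = cc[2],
                                         present = present))
      }
    }
  }
  list(nuclei = nuclei, cells = cells, truth = truth)
}

#' Agreement between tracked identities and ground truth
#'
#' Matches each reported track to the ground-truth identity it overlaps
#' most (by per-frame nearest centroid) and returns the fraction of
#' frame-level assignments consistent with that mapping.
#'
#' @param tracks A [track_cells()] result.
#' @param truth Ground-truth table from [simulate_tracking_movie()].
#' @param max_dist Maximum centroid distance (px) for a frame-level match.
#' @return Fraction in [0, 1].
#' @export
tracking_agreement <- function(tracks, truth, max_dist = 10) {
  total <- 0L; good <- 0L
  for (tr in tracks) {
    ids <- vapply(seq_len(nrow(tr)), function(r) {
      cand <- truth[truth$frame == tr$frame[r] & truth$present, ]
      if (nrow(cand) == 0L) return(NA_integer_)
      d <- sqrt((cand$x - tr$x[r])^2 + (cand$y - tr$y[r])^2)
      if (min(d) > max_dist) NA_integer_ else cand$id[which.min(d)]
    }, integer(1))
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L) next
    total <- total + length(ids)
    good <- good + max(table(ids))
  }
  if (total == 0L) return(0)
  good / total
}
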