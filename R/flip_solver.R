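#' FLIP model parameters
#'
#' Free parameters of the compartmentalized loss model: chromatin
#' association `k1` (pseudo-first-order, the true bimolecular rate times the
#' partner concentration), export `k2`, import `km2`, bleach decay `eta` and
#' initial cytoplasmic concentration `C0`. Diffusion `D` (shared by both
#' compartments) and dissociation `km1` are fixed, with provenance recorded.
#'
#' @param k1,k2,km2,eta,C0 Free parameters (all >= 0).
#' @param D,km1 Fixed parameters.
#' @param provenance Named character: provenance of the fixed parameters
#'   (`"fixed_from_frap"`, `"fixed_literature"`, `"fitted"`).
#' @return A `FlipParameters` list.
#' @export
flip_parameters <- function(k1, k2, km2, eta, C0, D = 19, km1 = 0.4,
                            provenance = c(D = "fixed_literature",
                                           km1 = "fixed_from_frap")) {
  vals <- c(k1 = k1, k2 = k2, km2 = km2, eta = eta, C0 = C0, D = D, km1 = km1)
  if (any(vals < 0)) stop("all FLIP parameters must be non-negative")
  structure(as.list(vals), provenance = provenance, class = "FlipParameters")
}

## Sparse generator of the linear method-of-lines system on a CompartmentGrid.
## State ordering: N_M over nuclear cells, N_I over nuclear cells, C over
## cytoplasmic cells. Exchange across the nuclear boundary is scaled by
## (shared interface length)/(cell area) = 1/h per full edge, which makes
## the total boundary flux independent of the grid spacing.
flip_generator <- function(params, grid, bleach_on = TRUE) {
  idx <- grid$index
  n_all <- length(idx$cells)
  nucl <- which(idx$nuclear); cyto <- which(!idx$nuclear)
  nN <- length(nucl); nC <- length(cyto)
  if (nN == 0L || nC == 0L) stop("grid must contain both compartments")
  state_of <- integer(n_all)           # cell -> mobile-state index
  state_of[nucl] <- seq_len(nN)
  state_of[cyto] <- 2L * nN + seq_len(nC)
  ns <- 2L * nN + nC

  h <- grid$h_um
  D <- params$D; k1 <- params$k1; km1 <- params$km1
  k2 <- params$k2; km2 <- params$km2
  eta <- if (bleach_on) params$eta else 0

  ## neighbour pairs on the full lattice
  pos <- cbind(idx$gr, idx$gc)
  key <- paste(pos[, 1], pos[, 2])
  lookup <- stats::setNames(seq_len(n_all), key)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }
  for (a in seq_len(n_all)) {
    for (d in list(c(1, 0), c(0, 1))) {
      nb <- lookup[paste(pos[a, 1] + d[1], pos[a, 2] + d[2])]
      if (is.na(nb)) next
      b <- unname(nb)
      sa <- state_of[a]; sb <- state_of[b]
      if (idx$nuclear[a] == idx$nuclear[b]) {
        cc <- D / h^2
        add(sa, sb, cc); add(sa, sa, -cc)
        add(sb, sa, cc); add(sb, sb, -cc)
      } else {
        nn <- if (idx$nuclear[a]) sa else sb   # nuclear mobile state
        cs <- if (idx$nuclear[a]) sb else sa   # cytoplasmic state
        f <- 1 / h
        add(nn, nn, -k2 * f); add(nn, cs, km2 * f)
        add(cs, nn, k2 * f);  add(cs, cs, -km2 * f)
      }
    }
  }
  ## binding kinetics in the nucleus
  mi <- seq_len(nN); bi <- nN + seq_len(nN)
  add(mi, mi, rep(-k1, nN)); add(mi, bi, rep(km1, nN))
  add(bi, mi, rep(k1, nN));  add(bi, bi, rep(-km1, nN))
  ## bleach sink on both nuclear states at the bleach point(s)
  if (eta > 0) {
    bl <- state_of[which(idx$bleach)]
    add(bl, bl, rep(-eta, length(bl)))
    add(bl + nN, bl + nN, rep(-eta, length(bl)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(ns, ns))
  list(A = A, nN = nN, nC = nC, nucl = nucl, cyto = cyto,
       state_of = state_of)
}

#' Steady-state initial condition of the FLIP model
#'
#' Prior to bleaching the system is assumed at steady state, which fixes the
#' nuclear concentrations in terms of the rates and the cytoplasmic
#' concentration: `N_M0 = km2 C0 / k2`, `N_I0 = k1 N_M0 / km1`.
#'
#' @param params A [flip_parameters()].
#' @param gen Internal generator structure (from a forward solve); users
#'   normally go through [solve_flip_forward()].
#' @return State vector at the prebleach steady state.
#' @keywords internal
flip_steady_state <- function(params, gen) {
  if (params$k2 <= 0) {
    if (params$C0 > 0)
      stop("steady-state relations undefined: k2 = 0 with C0 > 0")
    NM0 <- 0
  } else NM0 <- params$km2 * params$C0 / params$k2
  NI0 <- if (params$km1 > 0) params$k1 * NM0 / params$km1 else 0
  c(rep(NM0, gen$nN), rep(NI0, gen$nN), rep(params$C0, gen$nC))
}

#' Solve the compartmentalized FLIP model forward
#'
#' Method-of-lines solution of the coupled loss model on the coarse grid:
#' diffusion within each compartment, first-order chromatin binding in the
#' nucleus, import/export flux across the nuclear boundary and a bleach sink
#' acting on both nuclear states at the bleach point. Because the
#' discretized system is linear, each constant-coefficient interval is
#' propagated exactly by a matrix exponential (the bleach on/off schedule
#' alternates two precomputed propagators); `method = "lsoda"` integrates
#' the same system with a stiff ODE solver instead.
#'
#' @param params A [flip_parameters()].
#' @param grid A [discretize()]d geometry.
#' @param n_frames Number of recorded frames.
#' @param frame_interval Seconds between frames.
#' @param bleach_duration Seconds of bleaching after each frame (`<=
#'   frame_interval`; the remainder of the interval evolves without the
#'   sink). Scalar or per-frame vector.
#' @param state0 Optional initial state override (defaults to the prebleach
#'   steady state).
#' @param method `"expm"` (exact linear propagation) or `"lsoda"`.
#' @return A `FlipSolution`: list with `times`, `G` (cells x frames matrix
#'   of observed intensities: `N_M + N_I` for nuclear cells, `C` for
#'   cytoplasmic), `states` (full state matrix), `grid`, `params`.
#' @export
solve_flip_forward <- function(params, grid, n_frames = 150L,
                               frame_interval = 2, bleach_duration = 2,
                               state0 = NULL, method = c("expm", "lsoda")) {
  method <- match.arg(method)
  gen_on <- flip_generator(params, grid, bleach_on = TRUE)
  gen_off <- flip_generator(params, grid, bleach_on = FALSE)
  x <- state0 %||% flip_steady_state(params, gen_on)
  bdur <- rep_len(bleach_duration, n_frames)
  ns <- length(x)
  states <- matrix(0, ns, n_frames)
  states[, 1L] <- x
  if (method == "expm") {
    ## propagators are reused across frames with the same bleach duration
    cache <- new.env(parent = emptyenv())
    prop <- function(b) {
      key <- sprintf("%.12g", b)
      if (is.null(cache[[key]])) {
        P_on <- if (b > 0) as.matrix(Matrix::expm(gen_on$A * b)) else diag(ns)
        P_off <- if (frame_interval - b > 0)
          as.matrix(Matrix::expm(gen_off$A * (frame_interval - b))) else diag(ns)
        cache[[key]] <- P_off %*% P_on
      }
      cache[[key]]
    }
    for (k in seq_len(n_frames - 1L)) {
      x <- prop(bdur[k]) %*% x
      states[, k + 1L] <- x
    }
  } else {
    Aon <- as.matrix(gen_on$A); Aoff <- as.matrix(gen_off$A)
    for (k in seq_len(n_frames - 1L)) {
      seg <- function(A, t1) {
        if (t1 <= 0) return(x)
        sol <- deSolve::ode(as.numeric(x), c(0, t1),
                            function(tt, y, p) list(as.numeric(A %*% y)),
                            parms = NULL, method = "lsoda",
                            rtol = 1e-8, atol = 1e-10)
        sol[nrow(sol), -1L]
      }
      x <- seg(Aon, bdur[k]); x <- seg(Aoff, frame_interval - bdur[k])
      states[, k + 1L] <- x
    }
  }
  nN <- gen_on$nN
  idx <- grid$index
  G <- matrix(0, length(idx$cells), n_frames)
  G[idx$nuclear, ] <- states[seq_len(nN), , drop = FALSE] +
    states[nN + seq_len(nN), , drop = FALSE]
  G[!idx$nuclear, ] <- states[2L * nN + seq_len(gen_on$nC), , drop = FALSE]
  structure(list(times = (seq_len(n_frames) - 1L) * frame_interval,
                 G = G, states = states, grid = grid, params = params,
                 nN = nN, nC = gen_on$nC),
            class = "FlipSolution")
}

#' Area-weighted total signal of a forward solution
#'
#' With no bleaching (`eta = 0`) the total is conserved; with bleaching it
#' is non-increasing.
#'
#' @param sol A `FlipSolution`.
#' @return Numeric vector over frames (units: concentration x um^2).
#' @export
flip_total_mass <- function(sol) {
  colSums(sol$states) * sol$grid$h_um^2
}
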