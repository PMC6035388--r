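#' Quantify the zero-import/export assumption of the FRAP analysis
#'
#' The recovery-model fits assume nuclear exchange is negligible on the
#' recovery timescale. This check quantifies the error that assumption
#' introduces: a no-bleach variant of the compartmental loss model (rapid
#' diffusion, so the recovery is purely reactive) simulates the bleach-point
#' recovery on a typical synthetic cell, once with the supplied import and
#' export rates and once with both set to zero, and a single-reaction model
#' is fitted to each trace. Initial condition: uniform nuclear concentration
#' 1 carrying the Gaussian-exponential dip at the bleach point; the mobile
#' concentration is uniform and capped by the bleached minimum (any excess
#' free protein elsewhere would refill the spot diffusively rather than
#' reactively); the cytoplasm sits at its steady-state concentration.
#'
#' @param rates Named list with `k1`, `km1`, `k2`, `km2` (e.g. [rate_set()]).
#' @param placements Bleach placements to test (`"center"`,
#'   `"right_shifted"`).
#' @param K,r_e Bleach depth and effective radius of the dip (typical
#'   postbleach-profile values).
#' @param r_n Nominal bleach radius, um (default 1.232).
#' @param D Diffusion coefficient, um^2/s; set fast (default 1000) to force
#'   a reactive recovery.
#' @param t_max,dt Simulated recovery duration and sampling, seconds.
#' @param spec Base [geometry_spec()] for the typical cell.
#' @param seed Seed for the geometry builder.
#' @return An `AssumptionReport` data frame: one row per placement with
#'   `rate_with_transport`, `rate_without_transport`, `rel_diff_pct`.
#' @export
zero_transport_check <- function(rates, placements = c("center", "right_shifted"),
                                 K = 1.0, r_e = 1.8, r_n = 1.232, D = 1000,
                                 t_max = 15, dt = 0.06,
                                 spec = geometry_spec(), seed = 1L) {
  rows <- lapply(placements, function(pl) {
    sp <- spec
    sp$bleach$placement <- pl
    geom <- make_geometry(sp, seed = seed)
    grid <- discretize(geom)
    idx <- grid$index
    nucl <- which(idx$nuclear)
    ## bleach dip per grid cell: mean of the radial profile over its pixels
    ctr <- geom$bleach_center
    dip <- vapply(nucl, function(i) {
      px <- grid$cell_pixels[[i]]
      r_um <- sqrt((px[, 2] - 1 - ctr[1])^2 + (px[, 1] - 1 - ctr[2])^2) *
        geom$pixel_size
      mean(profile_model(r_um, K, r_e))
    }, 0)
    f_eq <- rates$km1 / (rates$k1 + rates$km1)
    cm <- min(min(dip), f_eq)          # uniform mobile pool, capped by the dip
    NM <- rep(cm, length(nucl))
    NI <- pmax(dip - cm, 0)
    run_arm <- function(k2, km2) {
      par <- flip_parameters(k1 = rates$k1, km1 = rates$km1, k2 = k2,
                             km2 = km2, eta = 0, C0 = 0, D = D)
      gen <- flip_generator(par, grid, bleach_on = FALSE)
      C0 <- if (km2 > 0) rates$k2 * f_eq / rates$km2 else 0
      state0 <- c(NM, NI, rep(C0, gen$nC))
      times <- seq(0, t_max, by = dt)
      sol <- solve_flip_forward(par, grid, n_frames = length(times),
                                frame_interval = dt, bleach_duration = 0,
                                state0 = state0)
      trace <- sol$G[idx$bleach, , drop = FALSE][1, ]
      curve <- recovery_curve(c(seq(-3, -1) * dt, times),
                              c(rep(1, 3), trace),
                              c(rep(TRUE, 3), rep(FALSE, length(times))),
                              bleach_duration = 0, validate = FALSE)
      fit <- fit_reaction(curve, 1L)
      unname(fit$parameters["k_off1"])
    }
    r_on <- run_arm(rates$k2, rates$km2)
    r_off <- run_arm(0, 0)
    data.frame(placement = pl,
               rate_with_transport = r_on,
               rate_without_transport = r_off,
               rel_diff_pct = abs(r_on - r_off) / r_off * 100)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("AssumptionReport", "data.frame")
  out
}

#' Residuals of a FRAP model fit
#'
#' Observed minus predicted values on the postbleach time grid for any of
#' the four recovery models.
#'
#' @param fit A [fit_result()] from the recovery fits.
#' @param curve The fitted [recovery_curve()].
#' @return Data frame with `time_s`, `observed`, `predicted`, `residual`.
#' @export
frap_residuals <- function(fit, curve) {
  pb <- postbleach_part(curve)
  p <- fit$parameters
  Q <- switch(
    fit$model_id,
    diffusion = frap_model_diffusion(pb$t, p["D_e"], fit$extra$K_RC,
                                     fit$extra$r_e, fit$extra$r_n),
    single_reaction = fit$extra$f0 +
      frap_model_reaction(pb$t, p["A1"], p["k_off1"], p["t0"]),
    double_reaction = fit$extra$f0 +
      frap_model_reaction(pb$t, p[c("A1", "A2")], p[c("k_off1", "k_off2")],
                          p["t0"]),
    reaction_diffusion = frap_forward_reaction_diffusion(
      pb$t, p["k_on"], p["k_off"], p["D1"], fit$extra$K_RC,
      fit$extra$r_e, fit$extra$r_n),
    stop("unknown model: ", fit$model_id))
  data.frame(time_s = pb$t, observed = pb$S, predicted = as.numeric(Q),
             residual = pb$S - as.numeric(Q))
}

#' Median residual trace over a cohort of cells
#'
#' @param residual_list List of [frap_residuals()] data frames on a shared
#'   time grid.
#' @return Data frame with `time_s` and `median_residual`.
#' @export
cohort_median_residuals <- function(residual_list) {
  m <- vapply(residual_list, `[[`, residual_list[[1]]$residual, "residual")
  data.frame(time_s = residual_list[[1]]$time_s,
             median_residual = apply(as.matrix(m), 1, stats::median))
}

#' Residuals of a FLIP model fit, grouped by spatial region
#'
#' Observed minus predicted gridded intensities, grouped into the bleach
#' point, the remainder of the nucleus and the cytoplasm — the grouping used
#' to check that no spatial region is systematically mis-fit.
#'
#' @param fitres A [fit_flip()] result.
#' @return List with `residuals` (cells x frames matrix), `times`, `groups`
#'   (per-cell `"B"`/`"N"`/`"C"`), and `summary`: data frame of the median
#'   residual per group and frame.
#' @export
flip_residuals <- function(fitres) {
  R <- fitres$grid$S - fitres$G
  groups <- fitres$grid$index$labels
  times <- fitres$grid$times
  summ <- do.call(rbind, lapply(c("B", "N", "C"), function(g) {
    rows <- R[groups == g, , drop = FALSE]
    data.frame(group = g, time_s = times,
               median_residual = apply(rows, 2, stats::median))
  }))
  list(residuals = R, times = times, groups = groups, summary = summ)
}
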