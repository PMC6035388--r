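#' Time-weighted sum of squares of error for a recovery curve
#'
#' Residuals between the postbleach data `S(t)` and model values `Q(t)` are
#' weighted by `1 / (t + integral(S))`, so early times — which carry the
#' information about fast rates — contribute more, while the integral of the
#' data in the denominator removes the singularity at `t = 0`. The integral
#' is evaluated by the composite trapezoid rule on the frame grid.
#'
#' @param curve A [recovery_curve()].
#' @param Q Model values on the postbleach time grid.
#' @return The weighted SSE (scalar).
#' @export
weighted_sse <- function(curve, Q) {
  pb <- postbleach_part(curve)
  if (length(pb$t) == 0L) stop("zero-length curve")
  stopifnot(length(Q) == length(pb$S))
  w <- wsse_weights(pb$t, pb$S)
  sum(w * (pb$S - Q)^2)
}

## per-point weights such that sum(w * resid^2) equals the time-weighted SSE
## integral; combines trapezoid quadrature weights with 1/(t + int S)
wsse_weights <- function(t, S) {
  if (length(t) < 2L) return(1)
  IS <- trapz(t, S)
  trapz_weights(t) / (t + IS)
}

## common scaffolding for Levenberg-Marquardt fits of Q(t; par) to the curve
## under the weighted SSE, with box bounds and deterministic multi-start.
lm_fit_wsse <- function(curve, model_fun, starts, lower, upper,
                        maxiter = 200) {
  pb <- postbleach_part(curve)
  sw <- sqrt(wsse_weights(pb$t, pb$S))
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- try(minpack.lm::nls.lm(
      par = p0,
      lower = lower, upper = upper,
      fn = function(p) sw * (pb$S - model_fun(pb$t, p)),
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-15, ptol = 1e-13)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || sum(fit$fvec^2) < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) return(NULL)
  list(par = best$par, wsse = sum(best$fvec^2),
       converged = best$info %in% 1:4)
}

## deterministic jitter factors for multi-start optimization
multistart <- function(p0, factors = c(1, 0.5, 2)) {
  lapply(factors, function(f) p0 * f)
}

#' Fit the series diffusion model to a recovery curve
#'
#' Single free parameter `D_e`, minimizing the time-weighted SSE with the
#' Levenberg-Marquardt algorithm; the initial guess of 19 um^2/s interpolates
#' measured nuclear diffusion of GFP multimers of comparable mass.
#'
#' @param curve A [recovery_curve()].
#' @param K_RC Bleach depth from the recovery curve ([bleach_depth_from_curve()]).
#' @param r_e,r_n Effective and nominal bleach radii, um.
#' @param D_init Initial guess (default 19 um^2/s).
#' @return A [fit_result()] with parameter `D_e`, plus mobile-fraction
#'   statistics in `extra`.
#' @export
fit_diffusion <- function(curve, K_RC, r_e, r_n, D_init = 19) {
  model <- function(t, p) frap_model_diffusion(t, abs(p[1]), K_RC, r_e, r_n)
  res <- lm_fit_wsse(curve, model, multistart(c(D_e = D_init)),
                     lower = c(D_e = 1e-4), upper = c(D_e = 1e4))
  if (is.null(res))
    return(fit_result("diffusion", c(D_e = NA_real_), noisy = TRUE,
                      plausible = FALSE, discarded_reason = "optimizer_failure"))
  fit_result("diffusion",
             parameters = c(D_e = unname(abs(res$par[1]))),
             units = c(D_e = "um^2/s"),
             weighted_sse = res$wsse,
             extra = list(K_RC = K_RC, r_e = r_e, r_n = r_n,
                          n_par = 1L, converged = res$converged,
                          mobile = mobile_fraction(curve)))
}

#' Fit exponential reaction models to a recovery curve
#'
#' Fits `f0 + sum_i A_i (1 - exp(-k_off_i (t - t0)))` with the baseline `f0`
#' fixed at the first postbleach sample. Initial guesses come from the
#' single-exponential pre-fit `y = alpha (1 - exp(-kappa t))`, itself seeded
#' from a coarse grid around `alpha ~ 0.3`, `kappa ~ 0.5`. For the double
#' reaction the fast rate is seeded from the first 30 percent of the
#' recovery and the slow rate from the final 30 percent, both read off the
#' smooth single-reaction fit.
#'
#' @param curve A [recovery_curve()].
#' @param n_reactions 1 or 2.
#' @return A [fit_result()] with parameters `A_i`, `k_off_i`, `t0`.
#' @export
fit_reaction <- function(curve, n_reactions = 1L) {
  stopifnot(n_reactions %in% 1:2)
  pb <- postbleach_part(curve)
  f0 <- pb$S[1L]
  pre <- exp_prefit(pb$t, pb$S - f0)

  if (n_reactions == 1L) {
    model <- function(t, p) f0 + frap_model_reaction(t, p[1], p[2], p[3])
    starts <- multistart(c(A1 = pre$alpha, k_off1 = pre$kappa, t0 = 0))
    starts <- lapply(starts, function(p) { p["t0"] <- 0; p })
    res <- lm_fit_wsse(curve, model, starts,
                       lower = c(A1 = 0, k_off1 = 1e-6, t0 = -2),
                       upper = c(A1 = 2, k_off1 = 100, t0 = 2))
    model_id <- "single_reaction"
  } else {
    r1 <- fit_reaction(curve, 1L)
    seeds <- double_reaction_seeds(pb$t, r1, f0)
    model <- function(t, p) f0 + frap_model_reaction(t, p[c(1, 2)], p[c(3, 4)], p[5])
    starts <- multistart(c(A1 = seeds$A / 2, A2 = seeds$A / 2,
                           k_off1 = seeds$k_fast, k_off2 = seeds$k_slow, t0 = 0))
    starts <- lapply(starts, function(p) { p["t0"] <- 0; p })
    res <- lm_fit_wsse(curve, model, starts,
                       lower = c(A1 = 0, A2 = 0, k_off1 = 1e-6, k_off2 = 1e-6, t0 = -2),
                       upper = c(A1 = 2, A2 = 2, k_off1 = 100, k_off2 = 100, t0 = 2))
    model_id <- "double_reaction"
  }
  if (is.null(res))
    return(fit_result(model_id, c(A1 = NA_real_), noisy = TRUE,
                      plausible = FALSE, discarded_reason = "optimizer_failure"))
  p <- res$par
  units <- stats::setNames(c(rep(c("", "1/s"), each = n_reactions), "s"),
                           names(p))
  fit_result(model_id, parameters = p, units = units,
             weighted_sse = res$wsse,
             extra = list(f0 = f0, n_par = length(p),
                          converged = res$converged,
                          mobile = mobile_fraction(curve)))
}

## exponential pre-fit y = alpha (1 - exp(-kappa t)), coarse grid
## seeded near alpha ~ 0.3, kappa ~ 0.5 then refined by LM.
exp_prefit <- function(t, y) {
  grid <- expand.grid(alpha = c(0.1, 0.3, 0.6, 1),
                      kappa = c(0.05, 0.2, 0.5, 1.5, 5))
  sse <- apply(grid, 1, function(g)
    sum((y - g[1] * (1 - exp(-g[2] * t)))^2))
  g0 <- as.numeric(grid[which.min(sse), ])
  fit <- try(minpack.lm::nls.lm(
    par = c(alpha = g0[1], kappa = g0[2]),
    lower = c(0, 1e-6), upper = c(2, 100),
    fn = function(p) y - p[1] * (1 - exp(-p[2] * t))), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(alpha = 0.3, kappa = 0.5))
  list(alpha = unname(fit$par[1]), kappa = unname(fit$par[2]))
}

## initial rate guesses for the double reaction: the fast component is
## assumed to deliver the first 30% of the recovery and the slow component
## the final 30%, with the crossing times read off the smooth single fit
double_reaction_seeds <- function(t, single_fit, f0) {
  A <- unname(single_fit$parameters["A1"])
  k <- unname(single_fit$parameters["k_off1"])
  if (!is.finite(A) || !is.finite(k) || A <= 0) {
    return(list(A = 0.3, k_fast = 1.5, k_slow = 0.1))
  }
  t30 <- -log(1 - 0.3) / k   # time the single fit reaches 30% of amplitude
  t70 <- -log(1 - 0.7) / k
  list(A = A,
       k_fast = -log(1 - 0.3) / max(t30 / 3, min(diff(t))),
       k_slow = -log(0.3) / max(t70 * 3, t70 + 1e-6) * 1)
}

#' Fit the reaction-diffusion model to a recovery curve
#'
#' Free parameters `k_on`, `k_off` and the free-state diffusion coefficient
#' `D1`; bound-state diffusion is fixed at `D2 = 0` (chromatin-bound
#' molecules do not move on this timescale). The forward model is the
#' numerical axisymmetric solution of [frap_forward_reaction_diffusion()]
#' with the Gaussian-exponential initial condition. Initial guesses are
#' `[19, kappa, kappa]` with `kappa` from the exponential pre-fit.
#'
#' @inheritParams fit_diffusion
#' @param n_r Radial resolution of the forward model (reduced by default for
#'   fitting speed; raise for final estimates).
#' @return A [fit_result()] with parameters `k_on`, `k_off`, `D1`.
#' @export
fit_reaction_diffusion <- function(curve, K_RC, r_e, r_n, n_r = 90L) {
  pb <- postbleach_part(curve)
  pre <- exp_prefit(pb$t, pb$S - pb$S[1L])
  model <- function(t, p)
    frap_forward_reaction_diffusion(t, p[1], p[2], p[3], K_RC, r_e, r_n,
                                    n_r = n_r, rtol = 1e-6, atol = 1e-8)
  p0 <- c(k_on = pre$kappa, k_off = pre$kappa, D1 = 19)
  res <- lm_fit_wsse(curve, model, list(p0),
                     lower = c(k_on = 1e-6, k_off = 1e-4, D1 = 0.01),
                     upper = c(k_on = 100, k_off = 100, D1 = 500),
                     maxiter = 80)
  if (is.null(res))
    return(fit_result("reaction_diffusion", c(k_on = NA_real_), noisy = TRUE,
                      plausible = FALSE, discarded_reason = "solver_failure"))
  fit_result("reaction_diffusion",
             parameters = res$par,
             units = c(k_on = "1/s", k_off = "1/s", D1 = "um^2/s"),
             weighted_sse = res$wsse,
             extra = list(D2 = 0, K_RC = K_RC, r_e = r_e, r_n = r_n,
                          n_par = 3L, converged = res$converged,
                          mobile = mobile_fraction(curve)))
}

## mobile fraction R = (f_oo - f0) / (f_i - f0) with f0 the first postbleach
## sample; clipped reporting handled by the caller
mobile_fraction <- function(curve) {
  f0 <- attr(curve, "S0"); f_i <- attr(curve, "f_i"); f_oo <- attr(curve, "f_oo")
  R <- (f_oo - f0) / (f_i - f0)
  list(R = R, f0 = f0, f_i = f_i, f_oo = f_oo)
}

#' Plausibility screen for fitted recovery models
#'
#' Discards fits whose parameter magnitudes are physically unrealistic:
#' diffusion coefficients above 60 um^2/s (approaching or exceeding the
#' mobility of a single GFP, a quarter the size of the tagged protein),
#' binding rates above 25 1/s (unresolvable at the frame rate), and
#' dissociation rates below 0.01 1/s (0.001 1/s in `"tead"` mode for the
#' slower chromatin-factor experiments), which would reflect spurious linear
#' trends.
#'
#' @param fit A [fit_result()].
#' @param mode `"default"` or `"tead"`.
#' @return The fit with `plausible` / `discarded_reason` updated.
#' @export
apply_plausibility_filters <- function(fit, mode = c("default", "tead")) {
  mode <- match.arg(mode)
  if (fit$noisy) return(fit)
  p <- fit$parameters
  koff_floor <- if (mode == "tead") 0.001 else 0.01
  reason <- NA_character_
  if (fit$model_id == "diffusion" && p["D_e"] > 60) {
    reason <- "diffusion_exceeds_GFP_bound"
  } else if (fit$model_id == "reaction_diffusion") {
    if (p["D1"] > 60) reason <- "diffusion_exceeds_GFP_bound"
    else if (any(p[c("k_on", "k_off")] > 25)) reason <- "rate_exceeds_frame_rate_bound"
    else if (p["k_off"] < koff_floor) reason <- "dissociation_below_detection"
  } else if (fit$model_id %in% c("single_reaction", "double_reaction")) {
    ko <- p[grep("^k_off", names(p))]
    if (any(ko > 25)) reason <- "rate_exceeds_frame_rate_bound"
    else if (any(ko < koff_floor)) reason <- "dissociation_below_detection"
  }
  fit$plausible <- is.na(reason)
  fit$discarded_reason <- reason
  fit
}

#' Model selection over fitted recovery models
#'
#' Computes `AIC = n log(SSE_w / n) + 2 (p + 1)` from the time-weighted SSE
#' under a least-squares likelihood, turns AIC differences into Akaike
#' weights over the plausible fits, and — when diffusion-containing models
#' are ruled out — runs the nested F-test
#' `F = ((SSE1 - SSE2) / (df1 - df2)) / (SSE2 / df2)`
#' between the single and double reaction. The double reaction is accepted
#' only when the F-test is significant (`p <= 0.05`) AND its Akaike weight
#' exceeds the single reaction's; otherwise the single reaction is retained.
#'
#' @param fits List of [fit_result()]s (any subset of the four models).
#' @param curve The fitted [recovery_curve()].
#' @param alpha F-test significance level (default 0.05).
#' @return List with `selected` (model id or `NA` when the curve is noisy),
#'   `fits` (AIC and Akaike weights filled in), `f_test`, `noisy`.
#' @export
select_model <- function(fits, curve, alpha = 0.05) {
  n <- sum(!curve$is_prebleach)
  ids <- vapply(fits, `[[`, "", "model_id")
  names(fits) <- ids
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!f$noisy && is.finite(f$weighted_sse)) {
      p <- f$extra$n_par %||% length(f$parameters)
      fits[[i]]$aic <- n * log(max(f$weighted_sse, 1e-300) / n) + 2 * (p + 1)
    }
  }
  ok <- vapply(fits, function(f) f$plausible && !f$noisy && is.finite(f$aic), TRUE)
  if (!any(ok))
    return(list(selected = NA_character_, fits = fits,
                f_test = NULL, noisy = TRUE))
  aics <- vapply(fits[ok], `[[`, 0, "aic")
  d <- aics - min(aics)
  w <- exp(-d / 2); w <- w / sum(w)
  for (nm in names(w)) fits[[nm]]$akaike_weight <- unname(w[nm])

  diffusion_like <- intersect(names(w), c("diffusion", "reaction_diffusion"))
  best <- names(w)[which.max(w)]
  f_test <- NULL
  selected <- best
  reactions_only <- length(diffusion_like) == 0L || !(best %in% diffusion_like)
  if (reactions_only && all(c("single_reaction", "double_reaction") %in% names(w))) {
    s1 <- fits[["single_reaction"]]; s2 <- fits[["double_reaction"]]
    df1 <- n - (s1$extra$n_par %||% 3L)
    df2 <- n - (s2$extra$n_par %||% 5L)
    Fstat <- ((s1$weighted_sse - s2$weighted_sse) / (df1 - df2)) /
      (s2$weighted_sse / df2)
    pval <- stats::pf(Fstat, df1 - df2, df2, lower.tail = FALSE)
    f_test <- list(F = Fstat, p.value = pval, df = c(df1 - df2, df2))
    selected <- if (pval <= alpha &&
                    s2$akaike_weight > s1$akaike_weight) "double_reaction"
    else "single_reaction"
  } else if (length(intersect(names(w), c("single_reaction", "double_reaction"))) == 1L &&
             reactions_only) {
    selected <- best
  }
  list(selected = selected, fits = fits, f_test = f_test, noisy = FALSE)
}

#' Dissociation rate reported by a selection
#'
#' The single reaction reports `k_off1`; when the double reaction is
#' selected the rate of the larger-amplitude component is reported (the
#' second rate is typically fast with very wide confidence intervals).
#'
#' @param selection A [select_model()] report.
#' @return Dissociation rate in 1/s, or `NA` for a noisy curve.
#' @export
selected_rate <- function(selection) {
  if (isTRUE(selection$noisy) || is.na(selection$selected)) return(NA_real_)
  f <- selection$fits[[selection$selected]]
  p <- f$parameters
  switch(selection$selected,
         single_reaction = unname(p["k_off1"]),
         double_reaction = unname(p[paste0("k_off", which.max(p[c("A1", "A2")]))]),
         reaction_diffusion = unname(p["k_off"]),
         diffusion = NA_real_)
}

#' Summarize a cohort of per-cell recovery fits
#'
#' Noisy cells — curves on which every model was discarded or the optimizer
#' failed — are assumed to have recovered too fast to resolve and are entered
#' at the large arbitrary placeholder rate of 3.5 1/s before medians are
#' taken. Boxplot statistics use the 10th and 90th percentiles.
#'
#' @param rates Numeric vector of per-cell selected rates (`NA` = noisy).
#' @param placeholder Placeholder rate for noisy cells (default 3.5 1/s).
#' @return List with `values` (placeholders substituted), `median`,
#'   `median_fitted_only`, `quantiles` (10/25/50/75/90 percent), `n_noisy`.
#' @export
summarize_cohort <- function(rates, placeholder = 3.5) {
  if (length(rates) == 0L) stop("empty cohort")
  noisy <- is.na(rates)
  values <- ifelse(noisy, placeholder, rates)
  list(values = values,
       median = stats::median(values),
       median_fitted_only = if (all(noisy)) NA_real_ else
         stats::median(rates[!noisy]),
       quantiles = stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9)),
       n_noisy = sum(noisy), n = length(values))
}

#' Half-time of recovery
#'
#' Time at which the curve first reaches halfway between the first
#' postbleach intensity and the steady state. Reported for descriptive
#' comparability only; half-times conflate diffusion, binding and geometry
#' and are never used for inference here.
#'
#' @param curve A [recovery_curve()].
#' @return Half-time in seconds (linear interpolation between frames).
#' @export
half_time <- function(curve) {
  pb <- postbleach_part(curve)
  target <- pb$S[1L] + (attr(curve, "f_oo") - pb$S[1L]) / 2
  idx <- which(pb$S >= target)[1L]
  if (is.na(idx) || idx == 1L) return(NA_real_)
  t1 <- pb$t[idx - 1L]; t2 <- pb$t[idx]
  s1 <- pb$S[idx - 1L]; s2 <- pb$S[idx]
  t1 + (target - s1) / (s2 - s1) * (t2 - t1)
}

#' Fit all four recovery models and select among them
#'
#' Convenience pipeline for one cell: bleach depth from the curve, the four
#' model fits, plausibility screening and model selection.
#'
#' @param curve A [recovery_curve()].
#' @param r_e,r_n Effective and nominal bleach radii, um.
#' @param mode Plausibility mode, see [apply_plausibility_filters()].
#' @param models Subset of models to fit (the reaction-diffusion forward
#'   model is the slow one).
#' @param s0_method Convention for the bleach-depth inversion, see
#'   [bleach_depth_from_curve()]; `"series"` matches the series diffusion
#'   model used for the fits.
#' @return A [select_model()] report with `K_RC` attached.
#' @export
fit_frap_curve <- function(curve, r_e, r_n, mode = "default",
                           models = c("diffusion", "reaction_diffusion",
                                      "single_reaction", "double_reaction"),
                           s0_method = "series") {
  nu0 <- r_e^2 / r_n^2
  S0 <- min(max(attr(curve, "S0"), 1e-6), 1)
  K_RC <- bleach_depth_from_curve(S0, nu0, method = s0_method)
  fits <- list()
  if ("diffusion" %in% models)
    fits <- c(fits, list(fit_diffusion(curve, K_RC, r_e, r_n)))
  if ("reaction_diffusion" %in% models)
    fits <- c(fits, list(fit_reaction_diffusion(curve, K_RC, r_e, r_n)))
  if ("single_reaction" %in% models)
    fits <- c(fits, list(fit_reaction(curve, 1L)))
  if ("double_reaction" %in% models)
    fits <- c(fits, list(fit_reaction(curve, 2L)))
  fits <- lapply(fits, apply_plausibility_filters, mode = mode)
  out <- select_model(fits, curve)
  out$K_RC <- K_RC
  out
}
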