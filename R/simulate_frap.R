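#' Ground-truth parameter set for forward simulation
#'
#' Unifies the kinetic symbols of the recovery and loss models for
#' simulation: chromatin binding (`k1`/`km1`, also written k_on/k_off in the
#' FRAP context), nuclear exchange (`k2` export, `km2` import), bleach decay
#' `eta`, diffusion `D`, cytoplasmic concentration `C0`, bleach depth `K`
#' and effective radius `r_e`.
#'
#' @param model_id For FRAP curves: `"diffusion"`, `"reaction_diffusion"`,
#'   `"single_reaction"` or `"double_reaction"`.
#' @param D Diffusion coefficient, um^2/s.
#' @param k1,km1 Association / dissociation rates, 1/s.
#' @param k2,km2 Export / import rates, 1/s.
#' @param eta Bleach decay rate at the bleach point, 1/s.
#' @param C0 Initial cytoplasmic concentration, arbitrary units.
#' @param K Bleach depth.
#' @param r_e Effective bleach radius, um.
#' @param amplitudes Recovery amplitudes for reaction models (second entry
#'   used by the double reaction).
#' @param km1_2 Second dissociation rate (double reaction).
#' @param t0 Time offset for reaction models, s.
#' @param noise_sd Additive Gaussian noise sd on normalized intensity.
#' @param seed Integer seed.
#' @return A `GroundTruth` list.
#' @export
ground_truth <- function(model_id = "single_reaction", D = 19,
                         k1 = 0.3, km1 = 0.5, k2 = 0.018, km2 = 0.017,
                         eta = 1.5, C0 = 1, K = 1, r_e = 1.8,
                         amplitudes = NULL, km1_2 = NULL, t0 = 0,
                         noise_sd = 0.02, seed = 1L) {
  stopifnot(D >= 0, k1 >= 0, km1 >= 0, k2 >= 0, km2 >= 0, eta >= 0, K >= 0)
  structure(list(model_id = model_id, D = D, k1 = k1, km1 = km1,
                 k2 = k2, km2 = km2, eta = eta, C0 = C0, K = K, r_e = r_e,
                 amplitudes = amplitudes, km1_2 = km1_2, t0 = t0,
                 noise_sd = noise_sd, seed = seed),
            class = "GroundTruth")
}

#' FRAP acquisition protocol
#'
#' Default: 3 prebleach frames, a 2.9 s bleach, then one frame every 60 ms
#' for 18 s (48 s and 100 s variants are used for slow constructs).
#'
#' @param dt Frame interval, s.
#' @param t_max Postbleach duration, s.
#' @param n_prebleach Number of prebleach frames.
#' @param bleach_duration Bleach duration, s.
#' @param r_n Nominal bleach radius, um.
#' @return A protocol list.
#' @export
frap_protocol <- function(dt = 0.06, t_max = 18, n_prebleach = 3L,
                          bleach_duration = 2.9, r_n = 0.995) {
  list(dt = dt, t_max = t_max, n_prebleach = n_prebleach,
       bleach_duration = bleach_duration, r_n = r_n)
}

#' Simulate a FRAP recovery curve under a chosen model
#'
#' The noiseless postbleach curve follows the chosen model's closed form
#' (series diffusion, exponential reactions) or, for the reaction-diffusion
#' model, the numerical radial forward solution. Reaction-model curves sit
#' on the baseline `f0` given by the series bleach-depth relation so the
#' initial value is consistent with `K` and `r_e`. Prebleach samples are 1.
#' Gaussian noise of sd `noise_sd` is added to every sample.
#'
#' @param truth A [ground_truth()]; `km1` is the (first) recovery rate,
#'   `k1`/`km1` the binding pair for reaction-diffusion, `D` the diffusion
#'   coefficient.
#' @param protocol A [frap_protocol()].
#' @return A [recovery_curve()] with the truth attached as attribute
#'   `truth`.
#' @export
simulate_frap_curve <- function(truth, protocol = frap_protocol()) {
  t_post <- seq(0, protocol$t_max, by = protocol$dt)
  nu0 <- truth$r_e^2 / protocol$r_n^2
  f0 <- frap_s0(truth$K, nu0, method = "series")
  Q <- switch(
    truth$model_id,
    diffusion = frap_model_diffusion(t_post, truth$D, truth$K,
                                     truth$r_e, protocol$r_n),
    single_reaction = {
      A <- (truth$amplitudes %||% (1 - f0))[1]
      f0 + frap_model_reaction(t_post, A, truth$km1, truth$t0)
    },
    double_reaction = {
      A <- truth$amplitudes %||% rep((1 - f0) / 2, 2)
      k2nd <- truth$km1_2 %||% (5 * truth$km1)
      f0 + frap_model_reaction(t_post, A, c(truth$km1, k2nd), truth$t0)
    },
    reaction_diffusion = frap_forward_reaction_diffusion(
      t_post, truth$k1, truth$km1, truth$D, truth$K, truth$r_e, protocol$r_n),
    stop("unknown model_id: ", truth$model_id))
  t_pre <- -protocol$bleach_duration - protocol$dt * (protocol$n_prebleach:1)
  times <- c(t_pre, t_post)
  values <- c(rep(1, protocol$n_prebleach), Q)
  set.seed(truth$seed)
  if (truth$noise_sd > 0)
    values <- values + stats::rnorm(length(values), 0, truth$noise_sd)
  curve <- recovery_curve(times, pmax(values, 0),
                          c(rep(TRUE, protocol$n_prebleach),
                            rep(FALSE, length(t_post))),
                          bleach_duration = protocol$bleach_duration,
                          roi_area = pi * protocol$r_n^2,
                          validate = FALSE)
  attr(curve, "truth") <- truth
  curve
}
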