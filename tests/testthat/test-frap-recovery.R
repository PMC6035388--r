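test_that("time-weighted SSE matches hand arithmetic and scales quadratically", {
  curve <- suppressWarnings(
    recovery_curve(c(-1, 0, 1), c(1, 0.5, 0.9), c(TRUE, FALSE, FALSE),
                   validate = FALSE))
  ## two postbleach points t = (0, 1), S = (0.5, 0.9), Q = (0.6, 0.8):
  ## I_S = 0.7 (trapezoid), weights 0.5/(t + 0.7)
  ## SSE = 0.5 * 0.01 / 0.7 + 0.5 * 0.01 / 1.7
  expect_equal(weighted_sse(curve, c(0.6, 0.8)),
               0.5 * 0.01 / 0.7 + 0.5 * 0.01 / 1.7, tolerance = 1e-12)
  ## perfect model
  expect_equal(weighted_sse(curve, c(0.5, 0.9)), 0)
  ## doubling the residuals quadruples the SSE
  expect_equal(weighted_sse(curve, c(0.7, 0.7)),
               4 * weighted_sse(curve, c(0.6, 0.8)), tolerance = 1e-12)
})

test_that("diffusion fit recovers the generating coefficient", {
  tr <- ground_truth(model_id = "diffusion", D = 10, K = 1, r_e = 1.8,
                     noise_sd = 0, seed = 1)
  pr <- frap_protocol()
  curve <- simulate_frap_curve(tr, pr)
  nu0 <- 1.8^2 / pr$r_n^2
  K_RC <- bleach_depth_from_curve(attr(curve, "S0"), nu0, "series")
  fit <- fit_diffusion(curve, K_RC, 1.8, pr$r_n)
  expect_lt(abs(fit$parameters["D_e"] / 10 - 1), 0.01)
  expect_lt(fit$weighted_sse, 1e-8)
})

test_that("reaction fits recover parameters and honour reparameterization", {
  pr <- frap_protocol()
  tr <- ground_truth(model_id = "single_reaction", km1 = 0.5, K = 1,
                     r_e = 1.8, amplitudes = 0.7, noise_sd = 0, seed = 1)
  curve <- simulate_frap_curve(tr, pr)
  fit <- fit_reaction(curve, 1L)
  expect_lt(abs(fit$parameters["A1"] / 0.7 - 1), 1e-4)
  expect_lt(abs(fit$parameters["k_off1"] / 0.5 - 1), 1e-4)
  expect_lt(abs(fit$parameters["t0"]), 1e-4)

  ## a time-shifted copy is a pure reparameterization: the rate is
  ## unchanged, the fit is exact, and (A, t0) satisfy the rigid-shift
  ## identity A_fit * exp(k t0_fit) = A * exp(k * 0.3) (the baseline anchor
  ## absorbs part of the shift into the amplitude)
  tr_shift <- tr; tr_shift$t0 <- 0.3
  fit_s <- fit_reaction(simulate_frap_curve(tr_shift, pr), 1L)
  k_s <- fit_s$parameters["k_off1"]
  expect_lt(abs(k_s / 0.5 - 1), 1e-3)
  expect_lt(fit_s$weighted_sse, 1e-10)
  lhs <- fit_s$parameters["A1"] * exp(k_s * fit_s$parameters["t0"])
  expect_lt(abs(lhs / (0.7 * exp(0.5 * 0.3)) - 1), 1e-3)

  ## double reaction on a true single-reaction curve degenerates:
  ## either one amplitude vanishes or the two rates coincide
  fit2 <- fit_reaction(curve, 2L)
  A <- fit2$parameters[c("A1", "A2")]
  k <- fit2$parameters[c("k_off1", "k_off2")]
  expect_true(min(A) < 0.02 * max(A) ||
                abs(k[1] - k[2]) < 0.05 * max(k))
})

test_that("reaction-diffusion fit recovers binding rates", {
  pr <- frap_protocol()
  tr <- ground_truth(model_id = "reaction_diffusion", k1 = 0.3, km1 = 0.5,
                     D = 15, K = 1, r_e = 1.8, noise_sd = 0, seed = 1)
  curve <- simulate_frap_curve(tr, pr)
  K_RC <- bleach_depth_from_curve(attr(curve, "S0"), 1.8^2 / pr$r_n^2, "series")
  fit <- fit_reaction_diffusion(curve, K_RC, 1.8, pr$r_n)
  expect_lt(abs(fit$parameters["k_on"] / 0.3 - 1), 0.05)
  expect_lt(abs(fit$parameters["k_off"] / 0.5 - 1), 0.05)
})

test_that("plausibility filters apply the published thresholds", {
  mk <- function(id, pars) fit_result(id, pars, weighted_sse = 1,
                                      extra = list(n_par = length(pars)))
  d_bad <- apply_plausibility_filters(mk("diffusion", c(D_e = 61)))
  expect_false(d_bad$plausible)
  expect_equal(d_bad$discarded_reason, "diffusion_exceeds_GFP_bound")
  expect_true(apply_plausibility_filters(mk("diffusion", c(D_e = 59)))$plausible)

  r_ok <- mk("single_reaction", c(A1 = 0.3, k_off1 = 0.02, t0 = 0))
  expect_true(apply_plausibility_filters(r_ok)$plausible)
  r_fast <- mk("single_reaction", c(A1 = 0.3, k_off1 = 26, t0 = 0))
  expect_equal(apply_plausibility_filters(r_fast)$discarded_reason,
               "rate_exceeds_frame_rate_bound")
  r_slow <- mk("single_reaction", c(A1 = 0.3, k_off1 = 0.005, t0 = 0))
  expect_false(apply_plausibility_filters(r_slow, "default")$plausible)
  expect_true(apply_plausibility_filters(r_slow, "tead")$plausible)
})

test_that("AIC weights and the nested F-test drive model selection", {
  curve <- simulate_frap_curve(ground_truth(model_id = "single_reaction",
                                            noise_sd = 0.02, seed = 3))
  n <- sum(!curve$is_prebleach)
  mk <- function(id, sse, p) fit_result(id, c(x = 1), weighted_sse = sse,
                                        extra = list(n_par = p))
  ## equal SSE and parameter count: weights (0.5, 0.5)
  sel <- select_model(list(mk("single_reaction", 1, 3),
                           mk("double_reaction", 1, 3)), curve)
  expect_equal(sel$fits$single_reaction$akaike_weight, 0.5, tolerance = 1e-12)
  ## delta AIC of 2: weights (0.731, 0.269)
  sse2 <- 1 * exp(2 / n)
  sel2 <- select_model(list(mk("diffusion", 1, 3), mk("single_reaction", sse2, 3)),
                       curve)
  w <- c(sel2$fits$diffusion$akaike_weight,
         sel2$fits$single_reaction$akaike_weight)
  expect_equal(w, exp(-c(0, 1)) / sum(exp(-c(0, 1))), tolerance = 1e-9)
  ## weights are invariant to the order of the model list
  sel2r <- select_model(list(mk("single_reaction", sse2, 3), mk("diffusion", 1, 3)),
                        curve)
  expect_equal(sel2r$fits$diffusion$akaike_weight, w[1], tolerance = 1e-12)

  ## F statistic arithmetic: SSE1 = 2, SSE2 = 1, df1 - df2 = 2, df2 = 10 -> F = 5
  short <- suppressWarnings(recovery_curve(
    c(-1, seq(0, 1.4, by = 0.1)), c(1, seq(0.5, 1, length.out = 15)),
    c(TRUE, rep(FALSE, 15)), validate = FALSE))
  self <- select_model(list(mk("single_reaction", 2, 3),
                            mk("double_reaction", 1, 5)), short)
  expect_equal(self$f_test$F, 5, tolerance = 1e-12)
  expect_equal(self$f_test$df, c(2, 10))

  ## all fits discarded: the curve is noisy
  bad <- mk("single_reaction", 1, 3)
  bad$plausible <- FALSE; bad$discarded_reason <- "rate_exceeds_frame_rate_bound"
  expect_true(select_model(list(bad), curve)$noisy)
})

test_that("model selection identifies the generating model on noiseless curves", {
  pr <- frap_protocol()
  cases <- list(
    list(truth = ground_truth(model_id = "diffusion", D = 10, K = 1,
                              r_e = 1.8, noise_sd = 0), expect = "diffusion"),
    list(truth = ground_truth(model_id = "diffusion", D = 30, K = 0.8,
                              r_e = 1.6, noise_sd = 0), expect = "diffusion"),
    list(truth = ground_truth(model_id = "single_reaction", km1 = 0.4, K = 1,
                              r_e = 1.8, noise_sd = 0), expect = "single_reaction"),
    list(truth = ground_truth(model_id = "single_reaction", km1 = 1.2, K = 0.7,
                              r_e = 1.6, noise_sd = 0), expect = "single_reaction"),
    list(truth = ground_truth(model_id = "double_reaction", km1 = 0.25,
                              km1_2 = 2.5, K = 1, r_e = 1.8,
                              amplitudes = c(0.35, 0.3), noise_sd = 0),
         expect = "double_reaction"),
    list(truth = ground_truth(model_id = "double_reaction", km1 = 0.15,
                              km1_2 = 1.5, K = 0.9, r_e = 1.8,
                              amplitudes = c(0.4, 0.25), noise_sd = 0),
         expect = "double_reaction"))
  hits <- vapply(cases, function(cs) {
    curve <- simulate_frap_curve(cs$truth, pr)
    sel <- fit_frap_curve(curve, r_e = cs$truth$r_e, r_n = pr$r_n)
    identical(sel$selected, cs$expect)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("selected-model residuals are trendless; diffusion misfit is not", {
  pr <- frap_protocol(t_max = 12)
  ## on well-specified single-reaction data the runs test is non-significant
  ## in at least 90% of seeds
  p_vals <- vapply(1:50, function(s) {
    curve <- simulate_frap_curve(
      ground_truth(model_id = "single_reaction", km1 = 0.5, K = 1, r_e = 1.8,
                   noise_sd = 0.02, seed = s), pr)
    fit <- fit_reaction(curve, 1L)
    nucshuttle:::runs_test(frap_residuals(fit, curve)$residual)$p.value
  }, 0)
  expect_gte(mean(p_vals > 0.05), 0.9)

  ## a pure-diffusion fit on reaction-type data (fast + slow release with a
  ## partially immobile pool, as in real recovery curves) underestimates the
  ## short-time recovery and overestimates the long-time recovery
  curves <- lapply(1:10, function(s) simulate_frap_curve(
    ground_truth(model_id = "double_reaction", km1 = 0.4, km1_2 = 8,
                 amplitudes = c(0.28, 0.2), K = 1, r_e = 1.8,
                 noise_sd = 0.02, seed = 100 + s), pr))
  res <- lapply(curves, function(cv) {
    K_RC <- bleach_depth_from_curve(min(attr(cv, "S0"), 1), 1.8^2 / pr$r_n^2,
                                    "series")
    frap_residuals(fit_diffusion(cv, K_RC, 1.8, pr$r_n), cv)
  })
  med <- cohort_median_residuals(res)
  early <- med$median_residual[med$time_s > 0.05 & med$time_s < 1]
  late <- med$median_residual[med$time_s > 2]
  expect_gt(mean(early), 0)
  expect_lt(mean(late), 0)
})

test_that("cohort summaries apply the noisy-cell placeholder convention", {
  expect_equal(summarize_cohort(rep(0.4, 5))$median, 0.4)
  s <- summarize_cohort(c(0.3, 0.4, 0.5, NA, NA))
  expect_equal(sort(s$values), c(0.3, 0.4, 0.5, 3.5, 3.5))
  expect_equal(s$median, 0.5)
  expect_equal(s$median_fitted_only, 0.4)
  expect_equal(s$n_noisy, 2L)
  expect_error(summarize_cohort(numeric(0)), "empty")
})

test_that("half-time is read off the curve by interpolation", {
  tr <- ground_truth(model_id = "single_reaction", km1 = 0.5, K = 1,
                     r_e = 1.8, noise_sd = 0, seed = 1)
  curve <- simulate_frap_curve(tr)
  ## half of (f_oo - S0) for a single exponential is reached at ~ln(2)/k
  expect_lt(abs(half_time(curve) - log(2) / 0.5), 0.1)
})
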