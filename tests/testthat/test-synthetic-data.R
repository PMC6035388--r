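test_that("geometry builder hits its targets and is deterministic", {
  g0 <- make_geometry(geometry_spec(n_nucleoli = 0L), seed = 3)
  expect_false(any(g0$nucleoli_mask))

  gd <- make_geometry(geometry_spec(eccentricity = 0, n_nucleoli = 0L), seed = 3)
  expect_lt(mask_shape_stats(gd$nucleus_mask)$eccentricity, 0.05)

  g <- make_geometry(geometry_spec(cyto_ratio = 1.5), seed = 5)
  ratio <- sum(g$cytoplasm_mask) / sum(g$nucleus_mask)
  expect_lt(abs(ratio / 1.5 - 1), 0.10)

  ## fixed seed gives bit-identical masks
  g2 <- make_geometry(geometry_spec(cyto_ratio = 1.5), seed = 5)
  expect_identical(g$nucleus_mask, g2$nucleus_mask)
  expect_identical(g$nucleoli_mask, g2$nucleoli_mask)
  expect_identical(g$bleach_roi, g2$bleach_roi)

  expect_error(make_geometry(geometry_spec(nucleus_area = 2000), seed = 1),
               "infeasible")
})

test_that("postbleach frame simulator follows the Gaussian-exponential profile", {
  expect_equal(profile_model(0, 1, 1), exp(-1))              # centre
  expect_equal(profile_model(1e3, 1, 1), 1)                  # far field
  expect_equal(profile_model(1, 1, 1), exp(-exp(-2)), tolerance = 1e-12)

  g <- std_geometry()
  fr <- simulate_postbleach_profile(K = 1.2, r_e = 1.5, g, noise_sd = 0)
  nuc <- g$nucleus_mask & !g$nucleoli_mask
  co <- nucshuttle:::pixel_coords(g$frame_shape)
  r <- sqrt((co$x - g$bleach_center[1])^2 +
            (co$y - g$bleach_center[2])^2) * g$pixel_size
  expect_equal(fr[nuc], profile_model(r[nuc], 1.2, 1.5), tolerance = 1e-12)
  ## unbleached outside the nucleus
  expect_true(all(fr[g$cytoplasm_mask] == 1))
})

test_that("FRAP curve simulator matches the closed-form models", {
  ## half of the amplitude is recovered at t = ln 2 / k
  expect_equal(frap_model_reaction(log(2) / 0.5, A = 0.8, k_off = 0.5), 0.4)
  ## diffusion model tends to 1
  expect_equal(frap_model_diffusion(1e7, 19, 1, 1.8, 1), 1, tolerance = 1e-4)
  ## double reaction with equal rates collapses onto a single reaction
  t <- seq(0, 18, by = 0.06)
  d2 <- frap_model_reaction(t, A = c(0.2, 0.3), k_off = c(0.4, 0.4))
  d1 <- frap_model_reaction(t, A = 0.5, k_off = 0.4)
  expect_lt(max(abs(d2 - d1)), 1e-12)

  tr <- ground_truth(model_id = "single_reaction", km1 = 0.5, K = 1,
                     r_e = 1.8, noise_sd = 0.02, seed = 11)
  c1 <- simulate_frap_curve(tr)
  c2 <- simulate_frap_curve(tr)
  expect_identical(c1$intensity, c2$intensity)   # fixed seed, bit-identical
  expect_error(simulate_frap_curve(ground_truth(model_id = "nope")), "unknown")
})

test_that("reaction-diffusion oracle matches its limiting closed forms", {
  t <- seq(0, 18, by = 0.06)
  ## k_on -> 0: pure diffusion series model, pointwise within 1%
  S_rd <- frap_forward_reaction_diffusion(t, k_on = 1e-9, k_off = 1, D1 = 10,
                                          K = 1, r_e = 1.2, r_n = 1)
  S_d <- frap_model_diffusion(t, D_e = 10, K = 1, r_e = 1.2, r_n = 1)
  expect_lt(max(abs(S_rd - S_d) / S_d), 0.01)

  ## D1 large: pseudo-first-order single reaction at rate k_off (after the
  ## sub-frame diffusive mixing transient, i.e. excluding t = 0)
  kon <- 0.3; koff <- 0.5
  feq <- koff / (kon + koff)
  S_fast <- frap_forward_reaction_diffusion(t, kon, koff, D1 = 3000,
                                            K = 1, r_e = 1.2, r_n = 1)
  s0w <- frap_s0(1, 1.44, "series")
  S_r <- feq + (1 - feq) * (1 - (1 - s0w) * exp(-koff * t))
  expect_lt(max(abs(S_fast[-1] - S_r[-1]) / S_r[-1]), 0.01)
})

test_that("FLIP simulator conserves mass and honours its limits", {
  g <- std_geometry()
  pr <- flip_protocol(n_frames = 60L)

  ## eta = 0: area-weighted total conserved
  tr0 <- caf_truth(noise_sd = 0); tr0$eta <- 0
  m0 <- simulate_flip_movie(tr0, g, pr)
  mass <- flip_total_mass(attr(m0, "solution"))
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-3)

  ## eta > 0: total non-increasing
  m1 <- simulate_flip_movie(caf_truth(noise_sd = 0), g, pr)
  expect_true(all(diff(flip_total_mass(attr(m1, "solution"))) <= 1e-9))

  ## k1 = 0, eta = 0, k2 = km2: symmetric steady state stays flat
  tr_eq <- ground_truth(k1 = 0, km1 = 0.4, k2 = 0.02, km2 = 0.02, eta = 0,
                        C0 = 1, D = 19, noise_sd = 0)
  meq <- simulate_flip_movie(tr_eq, g, flip_protocol(n_frames = 30L))
  expect_lt(max(abs(attr(meq, "solution")$G - 1)), 1e-9)

  ## very large eta: bleach-point intensity collapses within one frame
  ## (the residual level is the diffusion-resupply / sink balance)
  tr_eta <- caf_truth(noise_sd = 0); tr_eta$eta <- 5000
  meta <- simulate_flip_movie(tr_eta, g, flip_protocol(n_frames = 5L))
  sol <- attr(meta, "solution")
  b0 <- sol$G[sol$grid$index$bleach, 1]
  expect_lt(sol$G[sol$grid$index$bleach, 2] / b0, 0.01)

  ## slow-exchange regime (activated-fibroblast medians): the bleached point
  ## drains fastest, the cytoplasm is protected by the slow exchange, and the
  ## nuclear/cytoplasmic gap is wider than with normal-fibroblast medians
  gap <- function(sol) {
    labs <- sol$grid$index$labels
    nuc <- colMeans(sol$G[labs == "N", , drop = FALSE])
    cyt <- colMeans(sol$G[labs == "C", , drop = FALSE])
    bl <- sol$G[sol$grid$index$bleach, ]
    list(nuc = nuc / nuc[1], cyt = cyt / cyt[1], bl = bl / bl[1])
  }
  g_caf <- gap(attr(m1, "solution"))
  m_nf <- simulate_flip_movie(nf_truth(noise_sd = 0), g, pr)
  g_nf <- gap(attr(m_nf, "solution"))
  n_end <- length(g_caf$nuc)
  expect_lt(g_caf$bl[n_end], g_caf$nuc[n_end])      # bleached point fastest
  expect_gt(g_caf$cyt[n_end], g_caf$nuc[n_end])     # cytoplasm slowest
  expect_gt(mean(g_caf$cyt - g_caf$nuc), mean(g_nf$cyt - g_nf$nuc))

  ## fixed seed, bit-identical
  ma <- simulate_flip_movie(caf_truth(seed = 9), g, flip_protocol(n_frames = 10L))
  mb <- simulate_flip_movie(caf_truth(seed = 9), g, flip_protocol(n_frames = 10L))
  expect_identical(ma$frames, mb$frames)
})

test_that("FLIP simulator self-converges under grid refinement", {
  g <- fixture("small_geom", function()
    make_geometry(geometry_spec(nucleus_area = 110, cyto_ratio = 1.2,
                                n_nucleoli = 0L), seed = 4))
  tr <- caf_truth(noise_sd = 0)
  pr <- flip_protocol(n_frames = 40L)
  trace <- function(refine) {
    m <- simulate_flip_movie(tr, g, pr, refine = refine)
    apply(m$frames, 3, function(fr) mean(fr[g$bleach_roi]))
  }
  t1 <- trace(1); t2 <- trace(2); t4 <- trace(4)
  d12 <- max(abs(t1 - t2) / t2)
  d24 <- max(abs(t2 - t4) / t4)
  ## successive halvings shrink the discrepancy markedly (self-convergence)
  expect_lt(d24, d12 / 3)
  expect_lt(d24, 0.05)
})
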