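test_that("coarse gridding applies the 50 percent occupancy rule", {
  ## nucleus spans rows 5:24 of the 8-px lattice: the cell over rows 1:8 is
  ## half covered (rows 5:8) -> nuclear; shrinking coverage to 3 rows
  ## excludes it
  g50 <- tiny_geometry(nuc_rows = 5:24)
  gr50 <- discretize(g50)
  expect_equal(gr50$labels[1, 2], "N")
  g49 <- tiny_geometry(nuc_rows = 6:24)
  gr49 <- discretize(g49)
  expect_equal(gr49$labels[1, 2], "")
  expect_equal(gr50$labels[2, 2], "B")

  ## label counts agree with a brute-force pixel-counting oracle
  g <- std_geometry()
  gr <- discretize(g)
  nuc <- g$nucleus_mask & !g$nucleoli_mask
  oracle <- c(N = 0L, C = 0L)
  for (gi in seq_len(nrow(gr$labels))) for (gj in seq_len(ncol(gr$labels))) {
    rr <- (gr$offset[1] + (gi - 1) * gr$h_px + 1):(gr$offset[1] + gi * gr$h_px)
    cc <- (gr$offset[2] + (gj - 1) * gr$h_px + 1):(gr$offset[2] + gj * gr$h_px)
    fn <- mean(nuc[rr, cc]); fc <- mean(g$cytoplasm_mask[rr, cc])
    if (fn >= 0.5 && fn >= fc) oracle["N"] <- oracle["N"] + 1L
    else if (fc >= 0.5) oracle["C"] <- oracle["C"] + 1L
  }
  got <- table(gr$index$labels)
  expect_equal(unname(got["N"] + got["B"]), unname(oracle["N"]))
  expect_equal(unname(got["C"]), unname(oracle["C"]))

  ## uniform frame: all gridded intensities equal
  mv <- flip_movie(array(0.8, c(40, 40, 3)), frame_interval = 2)
  gru <- discretize(g50, mv)
  expect_true(all(abs(gru$S - 0.8) < 1e-12))
})

test_that("spatial weights equalize grid points and compartments", {
  times <- seq(0, 20, by = 2)
  nt <- length(times)
  labels <- c("B", "N", "N", "C", "C", "C")
  S <- rbind(exp(-0.5 * times),            # bleach point
             0.8 * exp(-0.1 * times),
             1.6 * exp(-0.1 * times),      # double the previous point
             seq(1, 0.9, length.out = nt),
             rep(0, nt),                   # dark grid point
             rep(1, nt))
  wf <- build_weights(S, times, labels)
  ## three-way equal compartment totals after re-weighting
  ct <- wf$ct
  tot <- vapply(c("B", "N", "C"), function(k)
    sum(wf$w[labels == k, , drop = FALSE] %*% ct), 0)
  expect_equal(unname(tot / tot[1]), rep(1, 3), tolerance = 1e-12)
  ## dark grid point gets zero weight
  expect_true(all(wf$w[5, ] == 0))
  ## doubling a grid point's intensity halves its weight (1 / integral(S))
  expect_equal(wf$w[2, ], 2 * wf$w[3, ], tolerance = 1e-12)
})

test_that("forward solutions are flat in the cytoplasm with a boundary jump", {
  fit0 <- caf_fit_noiseless()
  sol <- solve_flip_forward(fit0$params, fit0$grid, n_frames = 100L)
  ## walk one lattice row crossing cytoplasm -> nucleus -> cytoplasm
  gr <- fit0$grid
  idx <- gr$index
  row_cells <- which(idx$gr == idx$gr[idx$bleach][1])
  ord <- row_cells[order(idx$gc[row_cells])]
  vals <- sol$G[ord, 60]
  labs <- idx$labels[ord]
  ## largest step within the cytoplasm segment vs the N/C boundary jump
  cyt_steps <- abs(diff(vals[labs == "C"]))
  boundary <- which(labs[-1] != labs[-length(labs)])
  jump <- min(abs(vals[boundary + 1] - vals[boundary]))
  expect_gt(jump, 4 * max(cyt_steps))
  ## nuclear values dip toward the bleach point
  nuc_vals <- vals[labs != "C"]
  expect_lt(min(nuc_vals), min(vals[labs == "C"]))
})

test_that("ODE pre-fit recovers exchange magnitudes and falls back to defaults", {
  times <- seq(0, 298, by = 2)
  k2 <- 0.02; km2 <- 0.02; eta <- 1.0
  A <- matrix(c(-k2 - eta, km2, k2, -km2), 2, 2, byrow = TRUE)
  P <- as.matrix(Matrix::expm(A * 2))
  x <- c(1, 1); tr <- matrix(0, 2, length(times)); tr[, 1] <- x
  for (k in seq_along(times)[-1]) { x <- P %*% x; tr[, k] <- x }
  pf <- ode_prefit(tr[1, ], tr[2, ], times)
  expect_true(pf$converged)
  expect_lt(abs(pf$k2 / k2 - 1), 0.2)
  expect_lt(abs(pf$km2 / km2 - 1), 0.2)
  expect_lt(abs(pf$eta / eta - 1), 0.2)

  ## eta = 0 data fits eta ~ 0
  A0 <- matrix(c(-k2, km2, k2, -km2), 2, 2, byrow = TRUE)
  P0 <- as.matrix(Matrix::expm(A0 * 2))
  x <- c(1.5, 1); tr0 <- matrix(0, 2, length(times)); tr0[, 1] <- x
  for (k in seq_along(times)[-1]) { x <- P0 %*% x; tr0[, k] <- x }
  pf0 <- ode_prefit(tr0[1, ], tr0[2, ], times)
  expect_lt(pf0$eta, 0.01)

  ## flat traces: defaults, N/C ratio deciding which guess is larger
  flat_hi <- ode_prefit(rep(2, 10), rep(1, 10), seq(0, 18, by = 2))
  expect_false(flat_hi$converged)
  expect_gt(flat_hi$km2, flat_hi$k2)   # nuclear-enriched: import guessed larger
  flat_lo <- ode_prefit(rep(1, 10), rep(2, 10), seq(0, 18, by = 2))
  expect_gt(flat_lo$k2, flat_lo$km2)
  expect_equal(flat_hi$eta, 1.5)
})

test_that("the FLIP fit recovers all five free parameters", {
  fit0 <- caf_fit_noiseless()
  truth <- c(k1 = 0.235, k2 = 0.018, km2 = 0.017, eta = 1.5, C0 = 1)
  rel <- abs(fit0$fit$parameters[names(truth)] - truth) / truth
  expect_true(all(rel < 0.05))
  expect_false(fit0$fit$noisy)
})

test_that("the fitted point is the minimum of the weighted-SSE surface", {
  fit0 <- caf_fit_noiseless()
  p <- fit0$fit$parameters
  ## association/export surface: global minimum at the fit
  ks <- p["k1"] * c(0.6, 0.8, 1, 1.25, 1.6)
  es <- p["k2"] * c(0.6, 0.8, 1, 1.25, 1.6)
  m <- flip_sse_grid(fit0, "k1", "k2", ks, es)
  expect_equal(unname(arrayInd(which.min(m), dim(m))[1, ]), c(3L, 3L))

  ## import/export surface: minimum at the fit, with a shallow near-linear
  ## valley (the best import rises with export, tracking the N/C ratio)
  is_ <- p["km2"] * seq(0.6, 1.6, length.out = 7)
  es2 <- p["k2"] * seq(0.6, 1.6, length.out = 7)
  m2 <- flip_sse_grid(fit0, "km2", "k2", is_, es2)
  ij <- arrayInd(which.min(m2), dim(m2))
  expect_equal(unname(ij[1, 1]), which.min(abs(is_ - p["km2"])))
  best_import <- apply(m2, 2, which.min)
  expect_true(all(diff(best_import) >= 0) && best_import[7] > best_import[1])
})

test_that("parameter recovery holds across noisy replicate movies", {
  g <- std_geometry()
  pr <- flip_protocol(n_frames = 100L)
  errs <- sapply(1:5, function(s) {
    m <- simulate_flip_movie(caf_truth(noise_sd = 0.02, seed = 20 + s), g, pr)
    f <- fit_flip(m, g, fixed = list(D = 19, km1 = 0.40))
    p <- f$fit$parameters
    c(k1 = abs(p[["k1"]] / 0.235 - 1),
      k2 = abs(p[["k2"]] / 0.018 - 1),
      km2 = abs(p[["km2"]] / 0.017 - 1))
  })
  expect_lte(median(errs["k2", ]), 0.10)
  expect_lte(median(errs["km2", ]), 0.10)
  expect_lte(median(errs["k1", ]), 0.25)
})

test_that("fits are robust to halving the grid spacing", {
  g <- std_geometry()
  m <- simulate_flip_movie(caf_truth(noise_sd = 0.02, seed = 5), g,
                           flip_protocol(n_frames = 100L), refine = 2L)
  f1 <- fit_flip(m, g, fixed = list(D = 19, km1 = 0.40), refine = 1L)
  f2 <- fit_flip(m, g, fixed = list(D = 19, km1 = 0.40), refine = 2L)
  for (nm in c("k2", "km2")) {
    expect_lt(abs(f2$fit$parameters[[nm]] / f1$fit$parameters[[nm]] - 1), 0.10)
  }
})

test_that("import and export are insensitive to the fixed dissociation rate", {
  g <- std_geometry()
  m <- simulate_flip_movie(caf_truth(noise_sd = 0.01, seed = 31), g,
                           flip_protocol(n_frames = 100L))
  sw <- sensitivity_sweep(m, g, fixed = list(D = 19, km1 = 0.40),
                          vary = "km1", values = c(0.40, 0.20, 0.60))
  ## +/-50% dissociation moves import and export by well under 10%
  expect_lt(max(abs(sw$rel_k2[-1])), 0.10)
  expect_lt(max(abs(sw$rel_km2[-1])), 0.10)
  ## the association rate absorbs the change
  expect_gt(max(abs(sw$rel_k1[-1])), max(abs(sw$rel_k2[-1])))
  expect_gt(max(abs(sw$rel_k1[-1])), max(abs(sw$rel_km2[-1])))

  ## identical sweep values give identical fits (determinism)
  sw2 <- sensitivity_sweep(m, g, fixed = list(D = 19, km1 = 0.40),
                           vary = "km1", values = c(0.40, 0.40))
  expect_equal(sw2$k1[1], sw2$k1[2], tolerance = 1e-12)
  expect_equal(sw2$wsse[1], sw2$wsse[2], tolerance = 1e-12)
})

test_that("well-specified fits leave no compartment-level residual trend", {
  g <- std_geometry()
  m <- simulate_flip_movie(caf_truth(noise_sd = 0.02, seed = 41), g,
                           flip_protocol(n_frames = 100L))
  f <- fit_flip(m, g, fixed = list(D = 19, km1 = 0.40))
  rr <- flip_residuals(f)
  expect_setequal(unique(rr$summary$group), c("B", "N", "C"))
  for (grp in c("B", "N", "C")) {
    med <- rr$summary$median_residual[rr$summary$group == grp]
    expect_lt(max(abs(med)), 0.02)   # well within the noise floor
  }
  ## residual summaries are pure functions of (fit, data)
  expect_identical(flip_residuals(f)$summary, rr$summary)
})

test_that("degenerate steady states are rejected", {
  expect_error(
    solve_flip_forward(
      flip_parameters(k1 = 0.2, k2 = 0, km2 = 0.02, eta = 1, C0 = 1),
      discretize(std_geometry()), n_frames = 3L),
    "k2 = 0")
})
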