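## Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

std_geometry <- function() fixture("geom", function() {
  make_geometry(geometry_spec(), seed = 2L)
})

## CAF-regime FLIP ground truth at the published medians
caf_truth <- function(noise_sd = 0.02, seed = 1L) {
  ground_truth(k1 = 0.235, km1 = 0.40, k2 = 0.018, km2 = 0.017,
               eta = 1.5, C0 = 1, D = 19, noise_sd = noise_sd, seed = seed)
}

nf_truth <- function(noise_sd = 0.02, seed = 1L) {
  ground_truth(k1 = 0.25, km1 = 0.55, k2 = 0.046, km2 = 0.021,
               eta = 1.5, C0 = 1, D = 19, noise_sd = noise_sd, seed = seed)
}

## short noiseless CAF movie + its coarse fit, reused by several tests
caf_movie_noiseless <- function() fixture("caf_movie0", function() {
  simulate_flip_movie(caf_truth(noise_sd = 0, seed = 1L), std_geometry(),
                      flip_protocol(n_frames = 100L))
})

caf_fit_noiseless <- function() fixture("caf_fit0", function() {
  fit_flip(caf_movie_noiseless(), std_geometry(),
           fixed = list(D = 19, km1 = 0.40))
})

## simple hand geometry on a small frame: nucleus band containing the 8x8
## bleach square, cytoplasm band to the right
tiny_geometry <- function(nuc_rows = 5:24, frame = 40L) {
  nuc <- matrix(FALSE, frame, frame)
  nuc[nuc_rows, 9:16] <- TRUE
  cyt <- matrix(FALSE, frame, frame)
  cyt[5:24, 17:32] <- TRUE
  roi <- matrix(FALSE, frame, frame)
  roi[9:16, 9:16] <- TRUE
  cell_geometry(pixel_size = 0.264, nucleus_mask = nuc,
                cytoplasm_mask = cyt, bleach_roi = roi)
}
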