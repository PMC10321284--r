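# shared fixtures, built in code at test time

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# coarse axis covering the full diagnostic range; fast for image-level tests
coarse_axis <- function() build_spectral_axis(3850, 900, 16, 1L)

# short descending axis for MNF / toy-cube tests
toy_axis <- function(nb = 40, high = 2000, low = 1000)
  spectral_axis(seq(high, low, length.out = nb))

# cube with spatially smooth low-rank signal plus white noise, for MNF tests
rank_k_cube <- function(n = 30, nb = 40, rank = 3, noise_sd = 0.05,
                        seed = 42) {
  withr::with_seed(seed, {
    basis <- matrix(abs(rnorm(nb * rank)), nb, rank)
    r <- matrix(seq_len(n) / n, n, n)
    smooth <- list(sin(3 * r) + 1, cos(2 * t(r)) + 1, r * t(r),
                   sin(5 * t(r)) + 1, r^2 + t(r))
    w <- sapply(smooth[seq_len(rank)], as.vector)
    clean <- w %*% t(basis) + 1
    noisy <- clean + matrix(rnorm(n * n * nb, 0, noise_sd), n * n, nb)
    list(cube = hyper_cube(array(noisy, c(n, n, nb)), toy_axis(nb)),
         clean = clean, noise_sd = noise_sd)
  })
}

# small synthetic cohort used across image-level tests (10 patients, 2 TMAs)
small_cohort <- function(seed = 11, noise_sd = 0.008, jitter = 0.05,
                         paraffin = 0.05, axis = coarse_axis(),
                         keep_clean = FALSE) {
  cfg <- generator_config(n_tmas = 2L, cores_per_tma = 6L,
                          core_radius_px = 10L, n_patients = 10L,
                          overlap_fraction = 0.1,
                          noise_sd = noise_sd,
                          amplitude_jitter_cv = jitter,
                          paraffin_residual_amplitude = paraffin,
                          seed = seed)
  generate_cohort(cfg, axis = axis, keep_clean = keep_clean)
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
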