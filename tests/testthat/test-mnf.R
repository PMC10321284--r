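test_that("noise covariance of a constant cube is exactly zero", {
  ax <- toy_axis(8)
  cube <- hyper_cube(array(rep(1:8, each = 25), c(5, 5, 8)), ax)
  s <- estimate_noise_covariance(cube)
  expect_matrix_equal(s, matrix(0, 8, 8))
})

test_that("noise covariance matches a hand computation on a 2x3x2 toy cube", {
  ax <- toy_axis(2)
  # band 1 and band 2 values laid out as 2 rows x 3 cols
  b1 <- matrix(c(1, 2, 4, 8, 16, 32), 2, 3)
  b2 <- matrix(c(0, 1, 1, 0, 2, 2), 2, 3)
  cube <- hyper_cube(array(c(b1, b2), c(2, 3, 2)), ax)
  # horizontal half-differences (left - right)/sqrt(2), both rows, 2 gaps;
  # vertical (top - bottom)/sqrt(2), 3 columns
  dh1 <- c(b1[1, 1] - b1[1, 2], b1[2, 1] - b1[2, 2],
           b1[1, 2] - b1[1, 3], b1[2, 2] - b1[2, 3]) / sqrt(2)
  dh2 <- c(b2[1, 1] - b2[1, 2], b2[2, 1] - b2[2, 2],
           b2[1, 2] - b2[1, 3], b2[2, 2] - b2[2, 3]) / sqrt(2)
  dv1 <- (b1[1, ] - b1[2, ]) / sqrt(2)
  dv2 <- (b2[1, ] - b2[2, ]) / sqrt(2)
  d <- cbind(c(dh1, dv1), c(dh2, dv2))
  expected <- crossprod(d) / nrow(d)
  expect_matrix_equal(estimate_noise_covariance(cube), expected)
  expect_matrix_equal(
    estimate_noise_covariance(cube, direction = "horizontal"),
    crossprod(cbind(dh1, dh2)) / 4)
})

test_that("noise variance is recovered within 10% from 1e4 pixel pairs", {
  ax <- toy_axis(5)
  sigma <- 0.03
  withr::with_seed(13, {
    cube <- hyper_cube(
      array(1 + rnorm(101 * 101 * 5, 0, sigma), c(101, 101, 5)), ax)
  })
  s <- estimate_noise_covariance(cube)
  expect_true(all(abs(diag(s) - sigma^2) < 0.1 * sigma^2))
})

test_that("masking leaves no adjacent pair -> degenerate-input error", {
  ax <- toy_axis(4)
  cube <- hyper_cube(array(1, c(4, 4, 4)), ax)
  mask <- matrix(FALSE, 4, 4); mask[1, 1] <- TRUE; mask[3, 3] <- TRUE
  expect_error(estimate_noise_covariance(cube, mask), "no adjacent")
})

test_that("MNF eigen-spectrum separates a rank-3 signal from the noise floor", {
  fx <- rank_k_cube(rank = 3)
  m <- fit_mnf(fx$cube)
  expect_true(all(diff(m$eigenvalues) <= 1e-9))      # non-increasing SNR
  expect_gt(m$eigenvalues[3], 50)                    # signal components
  expect_lt(max(abs(m$eigenvalues[-(1:3)] - 1)), 0.6)  # near noise floor
  nb <- length(fx$cube$axis$wavenumbers)
  expect_matrix_equal(m$transform %*% m$inverse, diag(nb), tol = 1e-8)
  expect_matrix_equal(m$noise_covariance, t(m$noise_covariance))
  expect_matrix_equal(m$signal_covariance, t(m$signal_covariance))
})

test_that("pure white noise gives eigenvalues near 1", {
  ax <- toy_axis(10)
  withr::with_seed(17, {
    cube <- hyper_cube(array(5 + rnorm(40 * 40 * 10, 0, 0.1),
                             c(40, 40, 10)), ax)
  })
  ev <- fit_mnf(cube)$eigenvalues
  expect_true(all(abs(ev - 1) < 0.35))
})

test_that("k = bands reconstruction is the identity; error monotone in k", {
  fx <- rank_k_cube(rank = 3)
  nb <- length(fx$cube$axis$wavenumbers)
  full <- mnf_denoise(fx$cube, k = nb)
  expect_matrix_equal(full$data, fx$cube$data, tol = 1e-8)
  n2 <- prod(dim(fx$cube$data)[1:2])
  mse <- vapply(c(1, 3, 8, 20, nb), function(k) {
    d <- mnf_denoise(fx$cube, k = k)
    mean((matrix(d$data, n2, nb) - matrix(fx$cube$data, n2, nb))^2)
  }, numeric(1))
  # distance to the *observed* cube shrinks as k grows (projection property)
  expect_true(all(diff(mse) <= 1e-12))
  # and truncation at the true rank beats the raw cube against clean signal
  d3 <- mnf_denoise(fx$cube, k = 3)
  mse_raw <- mean((matrix(fx$cube$data, n2, nb) - fx$clean)^2)
  mse_den <- mean((matrix(d3$data, n2, nb) - fx$clean)^2)
  expect_lt(mse_den, mse_raw)
  expect_error(mnf_denoise(fx$cube, k = 0), "k must be")
  expect_error(mnf_denoise(fx$cube, k = nb + 1), "k must be")
})

test_that("MNF output is invariant to transposition of the scene", {
  fx <- rank_k_cube(rank = 2, n = 20, nb = 12)
  d <- mnf_denoise(fx$cube, k = 2)
  tcube <- fx$cube
  tcube$data <- aperm(fx$cube$data, c(2, 1, 3))
  dt <- mnf_denoise(tcube, k = 2)
  expect_matrix_equal(aperm(dt$data, c(2, 1, 3)), d$data, tol = 1e-8)
})

test_that("per-core denoising never leaks one core into another", {
  coh <- small_cohort(seed = 51)
  sc <- coh$tmas[[1]]
  man <- sc$manifest
  k <- 10
  base <- mnf_denoise_per_core(sc$cube, man, k = k)
  # perturb every pixel of core 1's footprint; core 2's output must be
  # bit-identical
  d <- dim(sc$cube$data)
  fpA <- core_footprint(man$cores[1, ], d[1], d[2])
  fpB <- core_footprint(man$cores[2, ], d[1], d[2])
  pert <- sc$cube
  arr <- pert$data
  arr[which(fpA) + rep((seq_len(d[3]) - 1) * d[1] * d[2],
                       each = sum(fpA))] <- 7
  pert$data <- arr
  out <- mnf_denoise_per_core(pert, man, k = k)
  mB <- matrix(base$data, d[1] * d[2], d[3])[as.vector(fpB), ]
  pB <- matrix(out$data, d[1] * d[2], d[3])[as.vector(fpB), ]
  expect_identical(mB, pB)
})

test_that("a single-core manifest reduces to whole-footprint denoising", {
  coh <- small_cohort(seed = 52)
  sc <- coh$tmas[[1]]
  core <- sc$manifest$cores[1, ]
  man1 <- tma_manifest(core, sc$manifest$patients)
  d <- dim(sc$cube$data)
  fp <- core_footprint(core, d[1], d[2])
  per_core <- mnf_denoise_per_core(sc$cube, man1, k = 8)
  direct <- mnf_denoise(sc$cube, mask = fp, k = 8)
  expect_equal(per_core$data, direct$data, tolerance = 1e-12)
})

test_that("per-core denoising reduces error to the clean scene in every core", {
  # cores large enough that per-core covariances are well determined
  # (pixels per core comfortably above the band count)
  cfg <- generator_config(n_tmas = 1L, cores_per_tma = 3L,
                          core_radius_px = 18L, n_patients = 3L,
                          overlap_fraction = 0, seed = 53)
  coh <- generate_cohort(cfg, axis = coarse_axis(), keep_clean = TRUE)
  sc <- coh$tmas[[1]]
  d <- dim(sc$cube$data)
  dn <- mnf_denoise_per_core(sc$cube, sc$manifest, k = 20)
  clean <- sc$ground_truth$clean
  for (i in seq_len(nrow(sc$manifest$cores))) {
    fp <- core_footprint(sc$manifest$cores[i, ], d[1], d[2])
    sel <- as.vector(fp)
    raw_mse <- mean((matrix(sc$cube$data, d[1] * d[2], d[3])[sel, ] -
                       matrix(clean, d[1] * d[2], d[3])[sel, ])^2)
    den_mse <- mean((matrix(dn$data, d[1] * d[2], d[3])[sel, ] -
                       matrix(clean, d[1] * d[2], d[3])[sel, ])^2)
    expect_lt(den_mse, raw_mse)
  }
})
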