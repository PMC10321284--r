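#' @title Minimum Noise Fraction denoising
#' @description MNF orders a noise-whitened eigenbasis of the data by
#'   signal-to-noise ratio; truncating the expansion to the leading `k`
#'   components and inverting removes most of the spatially uncorrelated
#'   noise while preserving spectral structure. Noise statistics come from
#'   half-differences of spatially adjacent pixels (the shift-difference
#'   estimator), so the transform must be fitted per core to avoid carrying
#'   one patient's statistics into another's reconstruction.
#' @name irhisto-mnf
NULL

# pairs of adjacent masked pixels as index pairs into the flattened image
.adjacent_pairs <- function(mask, direction = c("horizontal", "vertical")) {
  direction <- match.arg(direction)
  nr <- nrow(mask); nc <- ncol(mask)
  if (direction == "horizontal") {
    a <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
    idx <- which(a)
    r <- (idx - 1) %% nr + 1
    cc <- (idx - 1) %/% nr + 1
    cbind(r + (cc - 1) * nr, r + cc * nr)
  } else {
    a <- mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE]
    idx <- which(a)
    r <- (idx - 1) %% (nr - 1) + 1
    cc <- (idx - 1) %/% (nr - 1) + 1
    cbind(r + (cc - 1) * nr, r + 1 + (cc - 1) * nr)
  }
}

#' Estimate the band-by-band noise covariance of a cube
#'
#' Uses the shift-difference estimator: for adjacent masked pixel pairs the
#' half-difference `d = (x_left - x_right) / sqrt(2)` cancels the (locally
#' smooth) signal and retains the noise, so `cov(d)` estimates the noise
#' covariance. Horizontal and vertical neighbour pairs are pooled by
#' default, which makes the estimate symmetric under image transposition;
#' either direction alone is available.
#'
#' @param cube A `hyper_cube`.
#' @param mask Logical matrix of pixels to use (default: all).
#' @param direction `"both"` (default), `"horizontal"` or `"vertical"`.
#' @return Symmetric positive semi-definite bands x bands matrix.
#' @export
estimate_noise_covariance <- function(cube, mask = NULL,
                                      direction = c("both", "horizontal",
                                                    "vertical")) {
  direction <- match.arg(direction)
  nr <- dim(cube$data)[1]; nc <- dim(cube$data)[2]
  nb <- dim(cube$data)[3]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  x <- matrix(cube$data, nr * nc, nb)
  pairs <- switch(direction,
    horizontal = .adjacent_pairs(mask, "horizontal"),
    vertical = .adjacent_pairs(mask, "vertical"),
    both = rbind(.adjacent_pairs(mask, "horizontal"),
                 .adjacent_pairs(mask, "vertical")))
  if (nrow(pairs) < 1L)
    stop("no adjacent masked pixel pair: cannot estimate noise covariance",
         call. = FALSE)
  d <- (x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]) /
    sqrt(2)
  cov <- crossprod(d) / nrow(pairs)
  (cov + t(cov)) / 2
}

#' Fit an MNF model to a cube
#'
#' Computes the noise covariance (shift differences), the signal covariance
#' (sample covariance of masked pixels about their mean), and the
#' generalized eigenbasis of the pair via noise whitening. Components are
#' ordered by decreasing signal-to-noise eigenvalue; ties keep original
#' band-index order (the eigen routine's stable ordering).
#'
#' @param cube A `hyper_cube`.
#' @param mask Logical matrix of pixels contributing statistics
#'   (default: all).
#' @param regularize Ridge factor: `regularize * trace/bands` is added to
#'   the noise covariance diagonal when it is ill-conditioned.
#' @return An `mnf_model`: `noise_covariance`, `signal_covariance`,
#'   `transform` (bands x bands forward matrix, components in columns),
#'   `inverse` (its inverse), `eigenvalues` (decreasing SNR),
#'   `mean_spectrum`.
#' @export
fit_mnf <- function(cube, mask = NULL, regularize = 1e-8) {
  nr <- dim(cube$data)[1]; nc <- dim(cube$data)[2]
  nb <- dim(cube$data)[3]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  x <- matrix(cube$data, nr * nc, nb)[as.vector(mask), , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least 2 masked pixels", call. = FALSE)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sigma_s <- crossprod(xc) / (nrow(xc) - 1)
  sigma_n <- estimate_noise_covariance(cube, mask)
  # ridge the noise covariance so the whitening Cholesky exists
  ridge <- regularize * sum(diag(sigma_n)) / nb
  if (ridge <= 0) ridge <- regularize
  ch <- tryCatch(chol(sigma_n + diag(ridge, nb)), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(sigma_n + diag(1e-4 * max(diag(sigma_n), 1e-12), nb)),
                   error = function(e) NULL)
    if (is.null(ch))
      stop("noise covariance singular after regularization; ",
           "cannot whiten (condition of input data too degenerate)",
           call. = FALSE)
  }
  # whiten: W = inv(chol)' so W Sigma_n W' = I; eigendecompose whitened signal
  w <- backsolve(ch, diag(nb), transpose = TRUE)   # solves t(ch) %*% w = I
  m <- w %*% sigma_s %*% t(w)
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  transform <- t(eig$vectors) %*% w               # components in rows
  structure(list(
    noise_covariance = sigma_n, signal_covariance = sigma_s,
    transform = t(transform),                     # bands x comps (columns)
    inverse = solve(t(transform)),
    eigenvalues = eig$values,
    mean_spectrum = mu), class = "mnf_model")
}

#' Denoise a cube by truncated MNF reconstruction
#'
#' Projects every masked pixel onto the fitted MNF basis, zeroes all but the
#' first `k` components, and inverts the transform. Unmasked pixels pass
#' through unchanged. `k = 20` is the pipeline default.
#'
#' @param cube A `hyper_cube`.
#' @param mask Logical matrix (default: all pixels).
#' @param k Number of components kept, `1 <= k <= bands`.
#' @param model Optional pre-fitted `mnf_model`; fitted from `cube`/`mask`
#'   when omitted.
#' @return A denoised `hyper_cube` of identical shape and axis.
#' @export
mnf_denoise <- function(cube, mask = NULL, k = 20L, model = NULL) {
  nb <- dim(cube$data)[3]
  if (k < 1 || k > nb)
    stop(sprintf("k must be in [1, %d], got %s", nb, k), call. = FALSE)
  nr <- dim(cube$data)[1]; nc <- dim(cube$data)[2]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  if (is.null(model)) model <- fit_mnf(cube, mask)
  x <- matrix(cube$data, nr * nc, nb)
  sel <- as.vector(mask)
  xc <- sweep(x[sel, , drop = FALSE], 2, model$mean_spectrum)
  scores <- xc %*% model$transform[, seq_len(k), drop = FALSE]
  recon <- scores %*% model$inverse[seq_len(k), , drop = FALSE]
  x[sel, ] <- sweep(recon, 2, model$mean_spectrum, `+`)
  out <- cube
  out$data <- array(x, dim = c(nr, nc, nb))
  out
}

#' Core-by-core MNF denoising
#'
#' Fits and applies MNF independently inside every core footprint of the
#' manifest, so no statistic estimated from one core (patient) influences
#' another core's reconstruction. Cores whose footprint is too small to fit
#' the transform are passed through unchanged with a warning.
#'
#' @param cube A `hyper_cube`.
#' @param manifest A `tma_manifest` whose cores lie on this cube.
#' @param mask Optional logical matrix intersected with each core footprint.
#' @param k Components kept per core.
#' @return A denoised `hyper_cube`.
#' @export
mnf_denoise_per_core <- function(cube, manifest, mask = NULL, k = 20L) {
  nr <- dim(cube$data)[1]; nc <- dim(cube$data)[2]
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  out <- cube
  for (i in seq_len(nrow(manifest$cores))) {
    core <- manifest$cores[i, ]
    fp <- core_footprint(core, nr, nc) & mask
    # work on the core's bounding box only
    rows <- max(1L, core$center_row - core$radius_px + 1L):
      min(nr, core$center_row + core$radius_px + 1L)
    cols <- max(1L, core$center_col - core$radius_px + 1L):
      min(nc, core$center_col + core$radius_px + 1L)
    sub <- cube
    sub$data <- cube$data[rows, cols, , drop = FALSE]
    res <- tryCatch(
      mnf_denoise(sub, mask = fp[rows, cols, drop = FALSE], k = k),
      error = function(e) {
        warning(sprintf("core %s passed through undenoised: %s",
                        core$core_id, conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(res)) out$data[rows, cols, ] <- res$data
  }
  out
}
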