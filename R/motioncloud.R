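# Motion-cloud synthesis: bandpass-filtered spatiotemporal white noise.

fft_freqs <- function(n, spacing) {
  # signed frequencies in cycles per unit, FFT ordering
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * spacing)
}

#' Specify a motion-cloud stimulus
#'
#' Parameters of the non-rigid texture stimulus: white noise bandpass
#' filtered in the space-time frequency domain by the product of a
#' Gaussian envelope around the plane `fx Vx + fy Vy + ft = 0` (speed)
#' and a log-scale Gaussian envelope around the central spatial frequency
#' (all orientations included, yielding a toroidal spectrum).
#'
#' @param v_x,v_y Central velocity (deg/s); the study uses horizontal
#'   motion only (`v_y = 0`).
#' @param b_v Speed bandwidth (deg/s).
#' @param sf0 Central spatial frequency (cycles/deg).
#' @param b_sf Spatial-frequency bandwidth (cycles/deg).
#' @param n_px Frame size in pixels (square frames).
#' @param n_frames Number of frames.
#' @param frame_rate Frames per second.
#' @param deg_per_px Degrees of visual angle per pixel; the default spans
#'   a 50-degree field (25-degree radius) across the frame.
#' @return A list of class `motion_cloud_spec`.
#' @export
motion_cloud_spec <- function(v_x = 10, v_y = 0, b_v = 2.1, sf0 = 0.5,
                              b_sf = 0.5, n_px = 128, n_frames = 64,
                              frame_rate = 60, deg_per_px = 50 / n_px) {
  stopifnot(b_v > 0, sf0 > 0, b_sf > 0, n_px >= 8, n_frames >= 4,
            frame_rate > 0, deg_per_px > 0)
  structure(list(v_x = v_x, v_y = v_y, b_v = b_v, sf0 = sf0, b_sf = b_sf,
                 n_px = as.integer(n_px), n_frames = as.integer(n_frames),
                 frame_rate = frame_rate, deg_per_px = deg_per_px),
            class = "motion_cloud_spec")
}

# Real-valued spectral envelope on the FFT grid (DC excluded).
cloud_envelope <- function(spec) {
  fx <- fft_freqs(spec$n_px, spec$deg_per_px)          # cycles/deg
  fy <- fft_freqs(spec$n_px, spec$deg_per_px)
  ft <- fft_freqs(spec$n_frames, 1 / spec$frame_rate)  # Hz
  fr2 <- outer(fx^2, fy^2, `+`)                        # radial freq^2
  fr <- sqrt(fr2)
  log_bw <- log((spec$sf0 + spec$b_sf) / spec$sf0)
  radial <- array(0, dim(fr))
  nz <- fr > 0
  radial[nz] <- (1 / fr[nz]) *
    exp(-0.5 * (log(fr[nz] / spec$sf0) / log_bw)^2)
  plane <- outer(fx, fy, function(a, b) a * spec$v_x + b * spec$v_y)
  env <- array(0, c(spec$n_px, spec$n_px, spec$n_frames))
  for (k in seq_len(spec$n_frames)) {
    speed <- array(0, dim(fr))
    speed[nz] <- exp(-0.5 * ((plane[nz] + ft[k]) / (spec$b_v * fr[nz]))^2)
    env[, , k] <- radial * speed
  }
  # even-sized grids carry self-conjugate Nyquist bins that alias +f and
  # -f; averaging the envelope with its frequency-reversed copy keeps the
  # filter symmetric there, so filtering a real field stays real
  rev_idx <- function(n) c(1L, seq.int(n, 2L))
  (env + env[rev_idx(spec$n_px), rev_idx(spec$n_px),
             rev_idx(spec$n_frames)]) / 2
}

#' Synthesize a motion-cloud image stack
#'
#' Draws uniform white noise, shapes its 3-D Fourier spectrum with the
#' envelope described in [motion_cloud_spec()], and inverts the
#' transform. Filtering a real noise field keeps the spectrum Hermitian,
#' so the result is real up to floating-point residue; frames are
#' normalized to `[0, 1]` with the (excluded) DC component at mid-gray.
#'
#' @param spec A [motion_cloud_spec()].
#' @param seed Integer seed; a fixed seed gives a bit-identical stack.
#' @return An object of class `motion_cloud`: list with `frames` (array
#'   `n_px x n_px x n_frames` in `[0, 1]`), `spec`, `seed`, and
#'   `imag_residue` (max imaginary magnitude relative to signal RMS).
#' @export
motion_cloud <- function(spec = motion_cloud_spec(), seed = NULL) {
  stopifnot(inherits(spec, "motion_cloud_spec"))
  dims <- c(spec$n_px, spec$n_px, spec$n_frames)
  noise <- with_seed(seed, array(runif(prod(dims)) - 0.5, dims))
  Z <- stats::fft(noise)
  S <- Z * cloud_envelope(spec)
  img <- stats::fft(S, inverse = TRUE) / prod(dims)
  resid <- max(abs(Im(img))) / max(sqrt(mean(Re(img)^2)), .Machine$double.eps)
  x <- Re(img)
  rng <- range(x)
  frames <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) else x * 0 + 0.5
  structure(list(frames = frames, spec = spec, seed = seed,
                 imag_residue = resid),
            class = "motion_cloud")
}

#' Energy-weighted velocity estimate of an image stack
#'
#' Independent spectral check of the synthesized motion: fits the plane
#' `fx v_x + fy v_y + ft = 0` to the stack's power spectrum by weighted
#' least squares and returns the recovered `(v_x, v_y)`.
#'
#' @param cloud A [motion_cloud()] object.
#' @return Named numeric vector `c(v_x, v_y)` in deg/s.
#' @export
cloud_velocity_estimate <- function(cloud) {
  spec <- cloud$spec
  P <- abs(stats::fft(cloud$frames - mean(cloud$frames)))^2
  fx <- fft_freqs(spec$n_px, spec$deg_per_px)
  fy <- fft_freqs(spec$n_px, spec$deg_per_px)
  ft <- fft_freqs(spec$n_frames, 1 / spec$frame_rate)
  FX <- array(fx, dim(P))
  FY <- aperm(array(fy, dim(P)[c(2, 1, 3)]), c(2, 1, 3))
  FT <- aperm(array(ft, dim(P)[c(3, 1, 2)]), c(2, 3, 1))
  w <- as.vector(P)
  A <- cbind(as.vector(FX), as.vector(FY))
  b <- -as.vector(FT)
  keep <- w > 0 & (A[, 1]^2 + A[, 2]^2) > 0
  wls <- stats::lm.fit(A[keep, , drop = FALSE] * sqrt(w[keep]), b[keep] * sqrt(w[keep]))
  setNames(coef(wls), c("v_x", "v_y"))
}

#' Radial (spatial-frequency) energy spectrum of an image stack
#'
#' For each spatial frequency, takes the peak spectral power over
#' temporal frequency (the speed envelope's temporal width grows with
#' radial frequency, so the temporal *peak* — not the sum — isolates the
#' radial envelope), then sums over orientation into log-spaced
#' radial-frequency bins. With the log-scale envelope used by
#' [motion_cloud()], the resulting energy density over log-frequency
#' peaks at `sf0`.
#'
#' @param cloud A [motion_cloud()] object.
#' @param n_bins Number of log-spaced bins.
#' @return A tibble with `sf` (bin center, cycles/deg) and `energy`.
#' @export
cloud_radial_spectrum <- function(cloud, n_bins = 24) {
  spec <- cloud$spec
  P <- abs(stats::fft(cloud$frames - mean(cloud$frames)))^2
  fx <- fft_freqs(spec$n_px, spec$deg_per_px)
  fr <- sqrt(outer(fx^2, fx^2, `+`))
  pow_sp <- apply(P, c(1, 2), max)
  nz <- fr > 0
  lf <- log(fr[nz])
  breaks <- seq(min(lf), max(lf), length.out = n_bins + 1)
  bin <- cut(lf, breaks, include.lowest = TRUE, labels = FALSE)
  energy <- tapply(pow_sp[nz], bin, sum)
  centers <- exp((breaks[-1] + breaks[-length(breaks)]) / 2)
  tibble(sf = centers[as.integer(names(energy))],
         energy = as.numeric(energy))
}
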