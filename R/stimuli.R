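#' Orientation envelope of a Motion Cloud in the Fourier plane
#'
#' Evaluates the von Mises-shaped orientation envelope
#' \deqn{O(\theta, B_\theta) = \exp\{\cos(2(\theta_f - \theta)) / (4 B_\theta^2)\}}
#' at the frequency-component angles \code{freq_angle}. Angles and the
#' orientation bandwidth \eqn{B_\theta} are in radians; the envelope is
#' pi-periodic in both \code{theta} and \code{freq_angle}.
#'
#' Note that the denominator is \eqn{4 B_\theta^2}, not \eqn{B_\theta^2}: the
#' envelope concentration is therefore a factor 4 tighter than the nominal
#' von Mises rule \eqn{\kappa = 1/B_\theta^2}. This is intentional and kept
#' as-is so that generated textures match the published stimulus family.
#'
#' @param theta mean orientation (radians).
#' @param b_theta orientation bandwidth (radians), strictly positive.
#' @param freq_angle numeric vector (or array) of Fourier-plane angles (radians).
#' @return envelope values, same shape as \code{freq_angle}.
#' @examples
#' orientation_envelope(pi / 4, deg2rad(10), pi / 4) # maximum exp(1/(4 B^2))
#' @export
orientation_envelope <- function(theta, b_theta, freq_angle) {
  if (!is.numeric(b_theta) || length(b_theta) != 1L || !is.finite(b_theta) ||
      b_theta <= 0) {
    stop("`b_theta` must be a single positive number (radians).")
  }
  exp(cos(2 * (freq_angle - theta)) / (4 * b_theta^2))
}

#' Build one stimulus condition
#'
#' A \code{stimulus_spec} bundles the generative parameters of one Motion
#' Cloud condition: mean orientation, orientation bandwidth, drift direction
#' (orthogonal to the mean orientation), drift speed, spatial frequency,
#' display duration and contrast.
#'
#' @param theta mean orientation, degrees; wrapped into [0, 180).
#' @param b_theta orientation bandwidth, degrees; must be positive (the grid's
#'   "almost zero" value is 0.5 degrees, never exactly 0).
#' @param drift_direction +1 or -1, sign of drift orthogonal to \code{theta}.
#' @param drift_speed degrees of visual angle per second.
#' @param spatial_freq cycles per degree.
#' @param duration_ms display time in ms.
#' @param contrast fraction in (0, 1].
#' @return an object of class \code{stimulus_spec}.
#' @export
stimulus_spec <- function(theta, b_theta, drift_direction = 1L,
                          drift_speed = 10, spatial_freq = 0.9,
                          duration_ms = 300, contrast = 1.0) {
  if (b_theta <= 0) stop("`b_theta` must be > 0 degrees.")
  if (!drift_direction %in% c(-1L, 1L)) stop("`drift_direction` must be +1 or -1.")
  structure(
    list(theta = theta %% 180, b_theta = b_theta,
         drift_direction = as.integer(drift_direction),
         drift_speed = drift_speed, spatial_freq = spatial_freq,
         duration_ms = duration_ms, contrast = contrast),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf(
    "Motion Cloud spec: theta = %.1f deg, B_theta = %.1f deg, drift %+d (%.0f deg/s), %.2f cpd, %d ms\n",
    x$theta, x$b_theta, x$drift_direction, x$drift_speed, x$spatial_freq,
    as.integer(x$duration_ms)))
  invisible(x)
}

#' Synthesize Motion Cloud frames
#'
#' Generates a drifting band-pass filtered white-noise texture: white noise is
#' filtered in the Fourier plane by the product of the orientation envelope
#' (\code{\link{orientation_envelope}}) and a log-Gaussian radial
#' spatial-frequency envelope, then transformed back to the image domain.
#' Drift is implemented as a per-frame Fourier phase advance orthogonal to the
#' mean orientation. Frames are rescaled to [0, 1] over the whole stimulus
#' (full-contrast convention), so the per-frame mean luminance is constant.
#'
#' @param spec a \code{\link{stimulus_spec}}.
#' @param size_px image side in pixels (>= 32).
#' @param seed integer seed; identical \code{spec} + \code{seed} give
#'   bit-identical frames.
#' @param pixel_deg degrees of visual angle per pixel.
#' @param frame_rate_hz display frame rate.
#' @param sf_bandwidth_oct bandwidth (octaves) of the log-Gaussian radial
#'   envelope.
#' @return a \code{cloud_frames} object: list with \code{frames}
#'   (time x height x width array in [0, 1]), \code{pixel_deg} and \code{seed}.
#' @export
synthesize_cloud <- function(spec, size_px = 128L, seed = 1L,
                             pixel_deg = 0.1, frame_rate_hz = 60,
                             sf_bandwidth_oct = 1) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (size_px < 32L) stop("`size_px` must be >= 32.")
  n <- as.integer(size_px)
  n_frames <- max(1L, round(spec$duration_ms / 1000 * frame_rate_hz))

  # Fourier-plane coordinates in cycles/pixel.
  f1 <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  fx <- matrix(f1, n, n)                     # varies along rows
  fy <- t(fx)
  fr <- sqrt(fx^2 + fy^2)
  f_ang <- atan2(fy, fx)

  # peak-normalised orientation envelope (same shape as
  # orientation_envelope(); the exp(1/(4 B^2)) peak overflows for tiny B)
  b_rad <- deg2rad(spec$b_theta)
  env_ori <- exp((cos(2 * (f_ang - deg2rad(spec$theta))) - 1) / (4 * b_rad^2))
  f0 <- spec$spatial_freq * pixel_deg        # peak frequency, cycles/pixel
  sig <- sf_bandwidth_oct * log(2) / 2
  env_rad <- ifelse(fr > 0, exp(-(log(fr / f0))^2 / (2 * sig^2)) / fr, 0)
  envelope <- env_ori * env_rad
  envelope[1L, 1L] <- 0                      # zero-mean before normalisation

  set.seed(seed)
  noise <- matrix(stats::rnorm(n * n), n, n)
  base_fft <- stats::fft(noise) * envelope

  # Drift: translate by v pixels/frame orthogonal to the mean orientation.
  v_px <- spec$drift_direction * spec$drift_speed / frame_rate_hz / pixel_deg
  ang <- deg2rad(spec$theta + 90)
  dx <- v_px * cos(ang); dy <- v_px * sin(ang)
  shift1 <- exp(-2i * pi * (fx * dx + fy * dy))

  frames <- array(0, dim = c(n_frames, n, n))
  ph <- matrix(1 + 0i, n, n)
  for (k in seq_len(n_frames)) {
    frames[k, , ] <- Re(stats::fft(base_fft * ph, inverse = TRUE)) / (n * n)
    ph <- ph * shift1
  }
  rng <- range(frames)
  if (diff(rng) > 0) frames <- (frames - rng[1L]) / diff(rng)
  frames <- 0.5 + spec$contrast * (frames - 0.5)
  structure(list(frames = frames, pixel_deg = pixel_deg, seed = seed,
                 spec = spec),
            class = "cloud_frames")
}

#' @export
print.cloud_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Motion Cloud: %d frames of %dx%d px (%.3f deg/px), seed %d\n",
              d[1L], d[2L], d[3L], x$pixel_deg, x$seed))
  invisible(x)
}

# Angular profile of the Fourier amplitude spectrum of generated frames,
# used to verify that the realised orientation content broadens with B_theta.
#' Angular amplitude-spectrum profile of cloud frames
#'
#' Computes the mean Fourier amplitude as a function of orientation angle
#' (pi-periodic, binned), averaged over frames, together with the circular
#' variance of that angular profile. Useful to check the realised orientation
#' bandwidth of generated textures.
#'
#' @param cloud a \code{cloud_frames} object.
#' @param n_bins number of angular bins over [0, pi).
#' @return list with \code{angle} (bin centres, radians), \code{amplitude}
#'   and \code{circ_var}.
#' @export
angular_spectrum <- function(cloud, n_bins = 36L) {
  stopifnot(inherits(cloud, "cloud_frames"))
  fr <- cloud$frames
  n <- dim(fr)[2L]
  f1 <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  fx <- matrix(f1, n, n); fy <- t(fx)
  rr <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx) %% pi
  amp <- matrix(0, n, n)
  for (k in seq_len(dim(fr)[1L])) amp <- amp + Mod(stats::fft(fr[k, , ]))
  keep <- rr > 2 / n & rr <= 0.5
  bins <- pmin(floor(ang[keep] / pi * n_bins) + 1L, n_bins)
  prof <- as.numeric(tapply(amp[keep], factor(bins, levels = seq_len(n_bins)),
                            mean, default = 0))
  centres <- (seq_len(n_bins) - 0.5) * pi / n_bins
  cv <- 1 - Mod(sum(prof * exp(2i * centres)) / sum(prof))
  list(angle = centres, amplitude = prof, circ_var = cv)
}

#' Experimental stimulus grid
#'
#' Enumerates the stimulus conditions: \code{n_theta} mean orientations evenly
#' tiling [0, 180) degrees crossed with \code{n_btheta} orientation bandwidths
#' evenly spaced from (almost) 0 to \code{b_max} degrees. The smallest
#' bandwidth is replaced by \code{b_min} because the orientation envelope
#' divides by \eqn{B_\theta^2}. Defaults give the 96-condition design
#' (12 orientations x 8 bandwidths).
#'
#' @param n_theta number of mean orientations.
#' @param n_btheta number of orientation bandwidths.
#' @param b_min smallest bandwidth (degrees) standing in for "0".
#' @param b_max largest bandwidth (degrees).
#' @param spatial_freq cycles/degree, stored per condition.
#' @return data.frame with columns \code{stim_id}, \code{theta_deg},
#'   \code{b_theta_deg}, \code{sf_cpd}.
#' @seealso \code{\link{trial_table}}
#' @export
stimulus_grid <- function(n_theta = 12L, n_btheta = 8L, b_min = 0.5,
                          b_max = 35, spatial_freq = 0.9) {
  thetas <- seq(0, 180, length.out = n_theta + 1L)[seq_len(n_theta)]
  bthetas <- seq(0, b_max, length.out = n_btheta)
  bthetas[1L] <- b_min
  g <- expand.grid(theta_deg = thetas, b_theta_deg = bthetas,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(stim_id = seq_len(nrow(g)), g, sf_cpd = spatial_freq)
}

#' Full trial table
#'
#' Expands a stimulus grid with both drift directions and \code{n_trials}
#' repetitions per condition; the default design yields 96 x 2 x 15 = 2880
#' rows.
#'
#' @param grid output of \code{\link{stimulus_grid}}.
#' @param n_trials repetitions per (condition, drift) cell.
#' @return data.frame with one row per trial: \code{stim_id},
#'   \code{theta_deg}, \code{b_theta_deg}, \code{drift}, \code{trial}.
#' @export
trial_table <- function(grid = stimulus_grid(), n_trials = 15L) {
  out <- merge(
    merge(grid, data.frame(drift = c(-1L, 1L))),
    data.frame(trial = seq_len(n_trials))
  )
  out <- out[order(out$stim_id, out$drift, out$trial), ]
  rownames(out) <- NULL
  out
}

# ---- B_theta <-> kappa -------------------------------------------------------

KAPPA_MIN <- -log(0.5) / 2  # arccos argument leaves [-1, 1] below this

#' Convert von Mises concentration to orientation bandwidth
#'
#' Exact relation between the feedforward concentration \eqn{\kappa} and the
#' orientation bandwidth:
#' \deqn{B_\theta = \sqrt{0.5\,\arccos((\log 0.5 + \kappa)/\kappa) / (2 \log 2)}}
#' (radians). Defined for \eqn{\kappa \ge -\log(0.5)/2 \approx 0.3466};
#' \eqn{B_\theta \to 0} as \eqn{\kappa \to \infty}.
#'
#' @param kappa concentration parameter(s), \eqn{\ge -\log(0.5)/2}.
#' @return bandwidth in radians.
#' @export
btheta_from_kappa <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa < KAPPA_MIN)) {
    stop(sprintf("`kappa` must be >= -log(0.5)/2 = %.6f.", KAPPA_MIN))
  }
  sqrt(0.5 * acos((log(0.5) + kappa) / kappa) / (2 * log(2)))
}

#' Convert orientation bandwidth to von Mises concentration
#'
#' Numerical inverse of \code{\link{btheta_from_kappa}} by bracketed
#' root-finding on \eqn{\log \kappa}; round-trip error is below 1e-8.
#'
#' @param b_theta bandwidth in radians, in (0, \code{btheta_from_kappa(KAPPA_MIN)}).
#' @return concentration parameter kappa.
#' @export
kappa_from_btheta <- function(b_theta) {
  b_max <- btheta_from_kappa(KAPPA_MIN)
  vapply(b_theta, function(b) {
    if (!is.finite(b) || b <= 0 || b >= b_max) {
      stop(sprintf("`b_theta` must lie in (0, %.4f) radians.", b_max))
    }
    f <- function(lk) btheta_from_kappa(exp(lk)) - b
    exp(stats::uniroot(f, c(log(KAPPA_MIN) + 1e-9, log(1e12)),
                       tol = 1e-13)$root)
  }, numeric(1L))
}

#' Write a stimulus grid to CSV
#'
#' @param grid output of \code{\link{stimulus_grid}}.
#' @param path file path.
#' @export
write_stimulus_grid <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
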