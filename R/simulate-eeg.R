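#' Oscillatory ground truth for a simulated participant
#'
#' Describes the injected effects: a beta-band generator whose envelope drops
#' by `beta_suppression` (fractional power change) during the prediction
#' interval (movement onset to reappearance), and a delta-band generator whose
#' phase at stimulus disappearance is drawn from a von Mises distribution with
#' concentration `delta_kappa` (a phase reset without power change), both
#' projected to the sensors through the spherical forward model.
#'
#' @param beta_center_hz beta generator frequency (13--30 Hz).
#' @param beta_suppression fractional beta power change in `[-1, 0]` during
#'   the prediction interval.
#' @param delta_center_hz delta generator frequency (0.5--4 Hz).
#' @param delta_kappa von Mises concentration of the disappearance-locked
#'   delta phase (0 = no phase locking).
#' @param delta_preferred_phase preferred phase (radians).
#' @param beta_loc_mm,delta_loc_mm generator positions (mm, head frame).
#' @param noise_exponent 1/f^a exponent of the background EEG power spectrum.
#' @param snr generator-to-background RMS amplitude ratio (0 = background
#'   only).
#' @param dbs_freq_hz optional stimulation frequency; when set, a comb of
#'   sinusoidal artifacts at the frequency and its harmonics is added (to
#'   exercise the band-stop/low-pass stages).
#' @return object of class `oscillatory_truth`.
#' @export
oscillatory_truth <- function(beta_center_hz = 21, beta_suppression = -0.4,
                              delta_center_hz = 2, delta_kappa = 5,
                              delta_preferred_phase = 0,
                              beta_loc_mm = c(-35, -20, 55),
                              delta_loc_mm = c(0, -60, 40),
                              noise_exponent = 1, snr = 1,
                              dbs_freq_hz = NULL) {
  if (beta_center_hz < 13 || beta_center_hz > 30)
    stopf("beta_center_hz must lie in [13, 30]")
  if (delta_center_hz < 0.5 || delta_center_hz > 4)
    stopf("delta_center_hz must lie in [0.5, 4]")
  if (delta_kappa < 0) stopf("delta_kappa must be >= 0")
  if (beta_suppression < -1 || beta_suppression > 0)
    stopf("beta_suppression must lie in [-1, 0]")
  structure(list(beta_center_hz = beta_center_hz,
                 beta_suppression = beta_suppression,
                 delta_center_hz = delta_center_hz,
                 delta_kappa = delta_kappa,
                 delta_preferred_phase = delta_preferred_phase,
                 beta_loc_mm = beta_loc_mm, delta_loc_mm = delta_loc_mm,
                 noise_exponent = noise_exponent, snr = snr,
                 dbs_freq_hz = dbs_freq_hz),
            class = "oscillatory_truth")
}

# 1/f^a Gaussian noise, unit RMS, by spectral shaping of white noise
# (computed at an FFT-friendly padded length, then truncated)
.pink_noise <- function(n, exponent, fs) {
  m <- nextn(n, c(2, 3))
  w <- rnorm(m)
  W <- fft(w)
  f <- c(1e-9, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f) # two-sided
  H <- f^(-exponent / 2)
  H[1] <- 0
  x <- Re(fft(W * H, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

# von Mises draws by Best-Fisher rejection
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      fz <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - fz)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(fz)
        break
      }
    }
  }
  atan2(sin(out), cos(out))
}

# narrowband noise around f0 via FFT-domain Gaussian band selection
.narrowband_noise <- function(n, f0, bw, fs) {
  m <- nextn(n, c(2, 3))
  w <- rnorm(m)
  W <- fft(w)
  f <- seq(0, fs - fs / m, length.out = m)
  f2 <- pmin(f, fs - f)
  H <- exp(-(f2 - f0)^2 / (2 * (bw / 2)^2))
  x <- Re(fft(W * H, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

#' Simulate a continuous EEG recording for one session
#'
#' The signal is a sum of per-channel 1/f background noise and two focal
#' generators projected through the spherical head model: an ongoing
#' narrowband beta source whose envelope drops during each trial's prediction
#' interval, and a constant-amplitude delta oscillation whose free-running
#' phase is replaced, at each stimulus disappearance, by a von Mises draw.
#' Markers for all four task events are emitted.
#'
#' @param schedule a [build_schedule()] result.
#' @param truth an [oscillatory_truth()].
#' @param layout a [sensor_layout()].
#' @param design the [task_design()] (defaults to the schedule's).
#' @param head a [head_model()].
#' @param seed integer seed.
#' @param background_rms_uv background RMS per channel (microvolts).
#' @return object of class `tp_recording`: `signal` (channels x samples, uV),
#'   `fs`, `markers` (`data.frame` sample/label/trial_id), `layout`, `truth`,
#'   `schedule`.
#' @export
simulate_eeg <- function(schedule, truth = oscillatory_truth(),
                         layout = sensor_layout(), design = NULL,
                         head = head_model(), seed = 1L,
                         background_rms_uv = 10) {
  if (!nrow(schedule)) stopf("schedule is empty")
  design <- design %||% attr(schedule, "design")
  fs <- design$sampling_rate_hz
  pad_s <- ceiling((design$epoch_pad_ms + 100) * fs / 1000)
  n <- ceiling(max(schedule$t_offset) * fs / 1000) + pad_s
  nch <- length(layout$labels)
  for (loc in list(truth$beta_loc_mm, truth$delta_loc_mm))
    if (sqrt(sum((loc - head$center_mm)^2)) >= head$radius_mm)
      stopf("source location outside head radius")

  with_seed(seed, {
    sig <- matrix(0, nch, n)
    for (ch in seq_len(nch))
      sig[ch, ] <- background_rms_uv * .pink_noise(n, truth$noise_exponent, fs)

    if (truth$snr > 0) {
      t_axis <- (seq_len(n) - 1) / fs * 1000 # ms
      amp <- truth$snr * background_rms_uv

      # beta: ongoing narrowband source, envelope drop over prediction interval
      beta <- .narrowband_noise(n, truth$beta_center_hz, 4, fs)
      env <- rep(1, n)
      gain <- sqrt(1 + truth$beta_suppression)
      ramp_ms <- 100
      for (tr in seq_len(nrow(schedule))) {
        a <- schedule$t_move_on[tr]; b <- schedule$t_reappear[tr]
        inside <- t_axis >= a & t_axis <= b
        env[inside] <- gain
        up <- t_axis >= a - ramp_ms & t_axis < a
        env[up] <- 1 + (gain - 1) * (t_axis[up] - (a - ramp_ms)) / ramp_ms
        dn <- t_axis > b & t_axis <= b + ramp_ms
        env[dn] <- gain + (1 - gain) * (t_axis[dn] - b) / ramp_ms
      }
      beta <- beta * env
      topo_b <- dipole_topography(head, layout, truth$beta_loc_mm,
                                  .tangential_orientation(truth$beta_loc_mm))
      topo_b <- topo_b / sqrt(mean(topo_b^2))
      sig <- sig + amp * (topo_b %o% beta)

      # delta: phase-reset constant-amplitude oscillation
      theta <- .rvonmises(nrow(schedule), truth$delta_preferred_phase,
                          truth$delta_kappa)
      phase0 <- runif(1, -pi, pi)
      ph <- phase0 + 2 * pi * truth$delta_center_hz * t_axis / 1000
      resets <- schedule$t_disappear
      bounds <- c(resets, Inf)
      for (tr in seq_len(nrow(schedule))) {
        seg <- t_axis >= resets[tr] & t_axis < bounds[tr + 1]
        ph[seg] <- theta[tr] +
          2 * pi * truth$delta_center_hz * (t_axis[seg] - resets[tr]) / 1000
      }
      delta <- sqrt(2) * cos(ph) # unit RMS
      topo_d <- dipole_topography(head, layout, truth$delta_loc_mm,
                                  .tangential_orientation(truth$delta_loc_mm))
      topo_d <- topo_d / sqrt(mean(topo_d^2))
      sig <- sig + amp * (topo_d %o% delta)
    }

    if (!is.null(truth$dbs_freq_hz)) {
      t_s <- (seq_len(n) - 1) / fs
      comb <- 0
      for (h in seq_len(floor((fs / 2 - 1) / truth$dbs_freq_hz)))
        comb <- comb + sin(2 * pi * truth$dbs_freq_hz * h * t_s + runif(1, 0, 2 * pi)) / h
      sig <- sig + background_rms_uv * outer(rep(1, nch), comb)
    }
  })

  mk <- data.frame(
    sample = as.integer(round(c(schedule$t_move_on, schedule$t_disappear,
                                schedule$t_reappear, schedule$t_offset) *
                              fs / 1000)) + 1L,
    label = rep(c("move_on", "disappear", "reappear", "offset"),
                each = nrow(schedule)),
    trial_id = rep(schedule$trial_id, 4))
  mk <- mk[order(mk$sample), ]
  rownames(mk) <- NULL
  stopifnot(all(mk$sample >= 1), all(mk$sample <= n))
  rownames(sig) <- layout$labels
  structure(list(signal = sig, fs = fs, markers = mk, layout = layout,
                 truth = truth, schedule = schedule, head = head),
            class = "tp_recording")
}

# a unit tangential direction at a source position (EEG-visible orientation)
.tangential_orientation <- function(pos) {
  r <- pos / sqrt(sum(pos^2))
  ref <- if (abs(r[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * r) * r
  t1 / sqrt(sum(t1^2))
}

#' @export
print.tp_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s at %g Hz), %d markers\n",
              nrow(x$signal), ncol(x$signal), ncol(x$signal) / x$fs, x$fs,
              nrow(x$markers)))
  invisible(x)
}
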