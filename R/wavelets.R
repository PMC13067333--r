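#' Build a log-spaced Morlet wavelet bank
#'
#' Center frequencies are log-spaced between `f_min` and `f_max` and the
#' number of cycles grows log-spaced from `c_min` to `c_max` in step with
#' frequency. Each kernel is a Gaussian-windowed complex exponential with
#' temporal standard deviation \eqn{\sigma_t = cycles/(2\pi f)}, normalized to
#' unit energy by default so power is comparable across frequencies
#' (`normalization = "amplitude"` instead scales to gain 1 at the center
#' frequency).
#'
#' @param f_min,f_max frequency range (Hz); `f_max` must not exceed Nyquist.
#' @param n number of wavelets.
#' @param c_min,c_max cycle range.
#' @param fs sampling rate (Hz).
#' @param normalization `"energy"` (unit energy) or `"amplitude"`.
#' @param support_sd half-support of the kernel in units of \eqn{\sigma_t}.
#' @return object of class `wavelet_bank` with `freqs`, `cycles`, `kernels`
#'   (complex vectors, odd length), and `half_width_ms` (per-kernel temporal
#'   half support used for edge masking).
#' @export
build_bank <- function(f_min = 0.5, f_max = 100, n = 40, c_min = 2, c_max = 10,
                       fs = 1000, normalization = c("energy", "amplitude"),
                       support_sd = 3.5) {
  normalization <- match.arg(normalization)
  if (f_min <= 0 || f_min >= f_max) stopf("need 0 < f_min < f_max")
  if (f_max > fs / 2) stopf("f_max (%g) exceeds Nyquist (%g)", f_max, fs / 2)
  k <- seq_len(n) - 1
  freqs <- f_min * (f_max / f_min)^(k / (n - 1))
  cycles <- c_min * (c_max / c_min)^(k / (n - 1))
  sigma <- cycles / (2 * pi * freqs)           # seconds
  kernels <- vector("list", n)
  for (i in seq_len(n)) {
    half <- ceiling(support_sd * sigma[i] * fs)
    t <- (-half:half) / fs
    env <- exp(-t^2 / (2 * sigma[i]^2))
    g <- env * exp(2i * pi * freqs[i] * t)
    g <- g - env * (sum(g) / sum(env)) # zero mean: no DC leakage
    kernels[[i]] <- if (normalization == "energy")
      g / sqrt(sum(Mod(g)^2)) else g / sum(env) * 2
  }
  structure(list(freqs = freqs, cycles = cycles, kernels = kernels,
                 half_width_ms = support_sd * sigma * 1000, fs = fs,
                 normalization = normalization),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("Morlet bank: %d wavelets, %.3g-%.4g Hz, %g-%g cycles (%s norm, fs %g Hz)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), min(x$cycles),
              max(x$cycles), x$normalization, x$fs))
  invisible(x)
}

# FFT-based, center-aligned linear convolution of a channel x time matrix with
# one complex kernel; returns a matrix the size of the input.
.conv_channels <- function(sig_fft, nfft, nsamp, kernel) {
  L <- length(kernel)
  kf <- fft(c(kernel, rep(0, nfft - L)))
  y <- mvfft(sig_fft * kf, inverse = TRUE) / nfft
  off <- (L - 1) / 2
  y[off + seq_len(nsamp), , drop = FALSE]
}

#' Morlet decomposition of epoched data
#'
#' Convolves every trial and channel with each wavelet in the bank. To keep a
#' session-sized complex representation in memory, coefficients are retained
#' on a decimated time grid (default one sample per 20 ms); power and ITPC are
#' later computed on that grid and averaged within 100 ms bins. A per-frequency
#' validity rule marks samples whose distance to an epoch edge is smaller than
#' the kernel half-width.
#'
#' @param epochs a `tp_epochs` object (see [epoch_recording()]).
#' @param bank a [build_bank()] result at the epochs' sampling rate.
#' @param decim_ms spacing of retained coefficient samples (ms).
#' @return object of class `tp_tfr`: `coef` (per trial, channel x freq x time
#'   complex arrays), `times` (per trial, ms from epoch start), `events`
#'   (per-trial event latencies, ms from epoch start), `freqs`,
#'   `half_width_ms`, `step_ms`.
#' @export
tfr_convolve <- function(epochs, bank, decim_ms = 20) {
  if (abs(bank$fs - epochs$fs) > 1e-9) stopf("bank fs != epochs fs")
  step <- max(1L, round(decim_ms * epochs$fs / 1000))
  nf <- length(bank$freqs)
  Lmax <- max(lengths(bank$kernels))
  ntr <- length(epochs$trials)
  coef <- vector("list", ntr)
  times <- vector("list", ntr)
  for (tr in seq_len(ntr)) {
    x <- epochs$trials[[tr]]                       # channels x samples
    nsamp <- ncol(x)
    keep <- seq(1L, nsamp, by = step)
    nfft <- nextn(nsamp + Lmax - 1, 2)
    sf <- mvfft(rbind(t(x), matrix(0, nfft - nsamp, nrow(x))))
    arr <- array(0i, dim = c(nrow(x), nf, length(keep)))
    for (f in seq_len(nf)) {
      y <- .conv_channels(sf, nfft, nsamp, bank$kernels[[f]])
      arr[, f, ] <- t(y[keep, , drop = FALSE])
    }
    coef[[tr]] <- arr
    times[[tr]] <- (keep - 1) / epochs$fs * 1000
  }
  structure(list(coef = coef, times = times, events = epochs$events,
                 freqs = bank$freqs, half_width_ms = bank$half_width_ms,
                 step_ms = step / epochs$fs * 1000, fs = epochs$fs,
                 labels = epochs$layout$labels %||% rownames(epochs$trials[[1]])),
            class = "tp_tfr")
}

#' @export
print.tp_tfr <- function(x, ...) {
  cat(sprintf("Complex TFR: %d trials, %d channels, %d freqs (%.3g-%.4g Hz), step %g ms\n",
              length(x$coef), dim(x$coef[[1]])[1], length(x$freqs),
              min(x$freqs), max(x$freqs), x$step_ms))
  invisible(x)
}
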