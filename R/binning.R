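#' Canonical event-aligned analysis windows
#'
#' The four analysis windows, each aligned to its own task event, plus the
#' pre-movement normalization baseline. All bounds are in ms relative to the
#' aligning event and are multiples of the 100 ms bin grid offset.
#'
#' @return a data.frame with columns `window`, `event`, `start`, `end`.
#' @export
event_windows <- function() {
  data.frame(
    window = c("baseline", "movement", "disappearance", "reappearance",
               "norm_baseline"),
    event = c("move_on", "move_on", "disappear", "reappear", "move_on"),
    start = c(-550, -50, -350, -350, -500),
    end = c(-50, 950, 950, 450, -200),
    stringsAsFactors = FALSE)
}

.window_def <- function(window) {
  if (is.character(window)) {
    w <- event_windows()
    row <- w[w$window == window, ]
    if (nrow(row) != 1) stopf("unknown window '%s'", window)
    list(win = c(row$start, row$end), event = row$event, name = window)
  } else {
    list(win = window$win, event = window$event, name = window$name %||% "custom")
  }
}

# For each trial, indices of the decimated samples nearest to a common
# event-relative grid, plus per-frequency validity (edge mask).
.align_tfr <- function(tfr, win, event) {
  step <- tfr$step_ms
  grid <- seq(win[1] + step / 2, win[2], by = step)
  grid <- grid[grid < win[2]]
  ntr <- length(tfr$coef)
  idx <- matrix(NA_integer_, ntr, length(grid))
  valid <- matrix(TRUE, length(tfr$freqs), length(grid))
  for (tr in seq_len(ntr)) {
    ev <- tfr$events[[event]][tr]
    t0 <- tfr$times[[tr]][1]
    target <- ev + grid
    i <- round((target - t0) / step) + 1L
    bad <- i < 1L | i > length(tfr$times[[tr]])
    if (any(bad)) stopf("window [%g,%g] around '%s' leaves the epoch (trial %d)",
                        win[1], win[2], event, tr)
    idx[tr, ] <- i
    tt <- tfr$times[[tr]][i]
    dur <- tfr$times[[tr]][length(tfr$times[[tr]])]
    edge <- pmin(tt, dur - tt)                  # ms to nearest epoch edge
    valid <- valid & outer(tfr$half_width_ms, edge, `<=`)
  }
  list(grid = grid, idx = idx, valid = valid)
}

.bin_of <- function(grid, win, bin_ms) {
  nb <- (win[2] - win[1]) / bin_ms
  if (abs(nb - round(nb)) > 1e-9) stopf("window is not a whole number of bins")
  list(bin = pmin(as.integer(floor((grid - win[1]) / bin_ms)) + 1L, round(nb)),
       n = as.integer(round(nb)),
       centers = win[1] + (seq_len(round(nb)) - 0.5) * bin_ms)
}

.binned_map <- function(values, centers, valid, kind, event, freqs, labels,
                        n_trials, meta = list()) {
  structure(list(values = values, centers_ms = centers, valid = valid,
                 kind = kind, event = event, freqs = freqs, labels = labels,
                 n_trials = n_trials, meta = meta),
            class = "binned_map")
}

#' @export
print.binned_map <- function(x, ...) {
  cat(sprintf("Binned %s map (%s-aligned): %d channels x %d freqs x %d bins, %d trials\n",
              x$kind, x$event, dim(x$values)[1], dim(x$values)[2],
              dim(x$values)[3], x$n_trials))
  invisible(x)
}

#' Trial-averaged power in 100 ms bins for an event-aligned window
#'
#' Power is `|coefficient|^2`, averaged across trials per retained sample and
#' then across the samples of each 100 ms bin. Bins that contain any sample
#' inside a kernel's edge-contaminated zone (for any trial) are flagged
#' invalid at that frequency.
#'
#' @param tfr a [tfr_convolve()] result.
#' @param window a window name from [event_windows()] or a
#'   `list(win = c(start, end), event = ...)`.
#' @param bin_ms bin width (ms).
#' @return a `binned_map` (channels x freqs x bins) of kind `"power"`.
#' @export
power_binned <- function(tfr, window = "movement", bin_ms = 100) {
  wd <- .window_def(window)
  al <- .align_tfr(tfr, wd$win, wd$event)
  ntr <- length(tfr$coef)
  nch <- dim(tfr$coef[[1]])[1]; nf <- length(tfr$freqs)
  acc <- array(0, dim = c(nch, nf, length(al$grid)))
  for (tr in seq_len(ntr))
    acc <- acc + Mod(tfr$coef[[tr]][, , al$idx[tr, ], drop = FALSE])^2
  acc <- acc / ntr
  bn <- .bin_of(al$grid, wd$win, bin_ms)
  vals <- array(0, dim = c(nch, nf, bn$n))
  valid <- matrix(TRUE, nf, bn$n)
  for (b in seq_len(bn$n)) {
    sel <- bn$bin == b
    vals[, , b] <- apply(acc[, , sel, drop = FALSE], c(1, 2), mean)
    valid[, b] <- apply(al$valid[, sel, drop = FALSE], 1, all)
  }
  .binned_map(vals, bn$centers, valid, "power", wd$event, tfr$freqs,
              tfr$labels, ntr)
}

#' Inter-trial phase consistency in 100 ms bins
#'
#' ITPC is the resultant length of the unit phase vectors across trials,
#' \eqn{R = |N^{-1}\sum_n e^{i\phi_n}|}, computed per retained sample and then
#' averaged within each 100 ms bin (averaging ITPC values, not phases).
#'
#' @inheritParams power_binned
#' @return a `binned_map` of kind `"itpc"`, values in `[0, 1]`.
#' @export
itpc_binned <- function(tfr, window = "disappearance", bin_ms = 100) {
  wd <- .window_def(window)
  al <- .align_tfr(tfr, wd$win, wd$event)
  ntr <- length(tfr$coef)
  if (ntr < 2) stopf("ITPC needs at least 2 trials")
  nch <- dim(tfr$coef[[1]])[1]; nf <- length(tfr$freqs)
  acc <- array(0i, dim = c(nch, nf, length(al$grid)))
  for (tr in seq_len(ntr)) {
    z <- tfr$coef[[tr]][, , al$idx[tr, ], drop = FALSE]
    m <- Mod(z)
    m[m == 0] <- 1
    acc <- acc + z / m
  }
  R <- Mod(acc) / ntr
  bn <- .bin_of(al$grid, wd$win, bin_ms)
  vals <- array(0, dim = c(nch, nf, bn$n))
  valid <- matrix(TRUE, nf, bn$n)
  for (b in seq_len(bn$n)) {
    sel <- bn$bin == b
    vals[, , b] <- apply(R[, , sel, drop = FALSE], c(1, 2), mean)
    valid[, b] <- apply(al$valid[, sel, drop = FALSE], 1, all)
  }
  .binned_map(vals, bn$centers, valid, "itpc", wd$event, tfr$freqs,
              tfr$labels, ntr)
}

#' Baseline-normalize a binned power map
#'
#' @param map a `binned_map` of kind `"power"`.
#' @param baseline_map a `binned_map` holding the normalization baseline
#'   (typically [power_binned()] over the `"norm_baseline"` window).
#' @param mode `"relative"` ((P - mu)/mu), `"db"` (10 log10(P/mu)) or
#'   `"zscore"` ((P - mu)/sigma over baseline bins), per channel x frequency.
#' @return a `binned_map` of kind `"power_<mode>"`.
#' @export
baseline_normalize <- function(map, baseline_map,
                               mode = c("relative", "db", "zscore")) {
  mode <- match.arg(mode)
  mu <- apply(baseline_map$values, c(1, 2), mean)
  if (any(mu <= 0)) stopf("baseline mean power must be positive")
  vals <- map$values
  for (b in seq_len(dim(vals)[3])) {
    vals[, , b] <- switch(mode,
      relative = (map$values[, , b] - mu) / mu,
      db = 10 * log10(map$values[, , b] / mu),
      zscore = {
        sg <- apply(baseline_map$values, c(1, 2), sd)
        sg[sg == 0] <- NA
        (map$values[, , b] - mu) / sg
      })
  }
  out <- map
  out$values <- vals
  out$kind <- paste0("power_", mode)
  out$meta$baseline <- list(event = baseline_map$event,
                            centers_ms = baseline_map$centers_ms, mode = mode)
  out
}

#' Average a binned map over a frequency band and time window
#'
#' @param map a `binned_map`.
#' @param band_hz `c(lo, hi)`: frequencies with centers in `[lo, hi]`.
#' @param window_ms `c(lo, hi)`: bins with centers in `[lo, hi]` (default all).
#' @param use_valid drop frequency/bin cells flagged invalid.
#' @return named numeric vector, one value per channel.
#' @export
band_window_average <- function(map, band_hz, window_ms = NULL,
                                use_valid = TRUE) {
  fi <- which(map$freqs >= band_hz[1] & map$freqs <= band_hz[2])
  bi <- if (is.null(window_ms)) seq_along(map$centers_ms)
        else which(map$centers_ms >= window_ms[1] & map$centers_ms <= window_ms[2])
  if (!length(fi) || !length(bi)) stopf("empty band/window selection")
  sub <- map$values[, fi, bi, drop = FALSE]
  if (use_valid) {
    keep <- map$valid[fi, bi, drop = FALSE]
    if (!any(keep)) stopf("no valid cells in selection")
    out <- apply(sub, 1, function(m) mean(m[keep]))
  } else out <- apply(sub, 1, mean)
  names(out) <- map$labels
  out
}

#' Export a binned map as a long-format TSV
#' @param map a `binned_map`.
#' @param path output file.
#' @export
write_binned_map <- function(map, path) {
  d <- expand.grid(channel = map$labels %||% seq_len(dim(map$values)[1]),
                   freq_hz = map$freqs, bin_center_ms = map$centers_ms)
  d$value <- as.vector(map$values)
  d$valid <- as.vector(aperm(array(map$valid,
                c(dim(map$valid), dim(map$values)[1])), c(3, 1, 2)))
  d$kind <- map$kind
  d$event <- map$event
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
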