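# shared fixtures and independent oracles, all built in code

# minimal epochs object from a signal-generating function
make_epochs <- function(n_trials, n_channels, n_samples, fs,
                        signal_fun = function(tr, t) {
                          matrix(rnorm(n_channels * length(t)), n_channels)
                        },
                        events = NULL) {
  t <- (seq_len(n_samples) - 1) / fs
  trials <- lapply(seq_len(n_trials), function(tr) signal_fun(tr, t))
  if (is.null(events)) {
    mid <- n_samples / fs * 1000 / 2
    events <- data.frame(trial_id = seq_len(n_trials), move_on = mid,
                         disappear = mid, reappear = mid, offset = mid)
  }
  structure(list(trials = trials, events = events, fs = fs, layout = NULL),
            class = "tp_epochs")
}

# minimal ComplexTFR carrying externally supplied coefficients
make_tfr <- function(coef_list, fs, step_ms, freqs,
                     half_width_ms = rep(0, length(freqs)), events = NULL) {
  nt <- dim(coef_list[[1]])[3]
  times <- lapply(coef_list, function(a) (seq_len(nt) - 1) * step_ms)
  if (is.null(events)) {
    mid <- (nt - 1) * step_ms / 2
    events <- data.frame(trial_id = seq_along(coef_list), move_on = mid,
                         disappear = mid, reappear = mid, offset = mid)
  }
  structure(list(coef = coef_list, times = times, events = events,
                 freqs = freqs, half_width_ms = half_width_ms,
                 step_ms = step_ms, fs = fs, labels = NULL),
            class = "tp_tfr")
}

# brute-force flood-fill connected components (independent of the
# union-find implementation under test)
flood_fill_clusters <- function(sgn, dims, neighbors, freq_adj = TRUE,
                                time_adj = TRUE) {
  nnode <- dims[1]; nf <- dims[2]; nt <- dims[3]
  idx <- function(v, f, t) v + nnode * ((f - 1) + nf * (t - 1))
  lab <- integer(length(sgn))
  nxt <- 0
  for (t0 in seq_len(nt)) for (f0 in seq_len(nf)) for (v0 in seq_len(nnode)) {
    i <- idx(v0, f0, t0)
    if (sgn[i] == 0 || lab[i] != 0) next
    nxt <- nxt + 1
    queue <- list(c(v0, f0, t0))
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      v <- cur[1]; f <- cur[2]; tt <- cur[3]
      s <- sgn[idx(v, f, tt)]
      cand <- lapply(neighbors[[v]], function(w) c(w, f, tt))
      if (freq_adj) {
        if (f > 1) cand <- c(cand, list(c(v, f - 1, tt)))
        if (f < nf) cand <- c(cand, list(c(v, f + 1, tt)))
      }
      if (time_adj) {
        if (tt > 1) cand <- c(cand, list(c(v, f, tt - 1)))
        if (tt < nt) cand <- c(cand, list(c(v, f, tt + 1)))
      }
      for (nb in cand) {
        j <- idx(nb[1], nb[2], nb[3])
        if (sgn[j] == s && lab[j] == 0) {
          lab[j] <- nxt
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}

# truncated Legendre-series surface potential for a dipole in a homogeneous
# sphere (independent of the closed-form implementation)
series_sphere_potential <- function(e_unit, r0, p, a, sigma, nterm = 800) {
  b <- sqrt(sum(r0^2)); f <- b / a
  if (f < 1e-12) return(3 * sum(e_unit * p) / (4 * pi * sigma * a^2))
  b0 <- r0 / b
  cth <- sum(e_unit * b0)
  sth <- sqrt(max(0, 1 - cth^2))
  pr <- sum(p * b0)
  th <- if (sth > 1e-12) (e_unit - cth * b0) / sth else c(0, 0, 0)
  pt <- sum(p * th)
  tot <- 3 * (pr * cth + pt * sth)
  Pnm1 <- 1; Pn <- cth; Qnm1 <- 0; Qn <- sth
  for (n in 2:nterm) {
    Pnp <- ((2 * n - 1) * cth * Pn - (n - 1) * Pnm1) / n
    Qnp <- ((2 * n - 1) * cth * Qn - n * Qnm1) / (n - 1)
    Pnm1 <- Pn; Pn <- Pnp; Qnm1 <- Qn; Qn <- Qnp
    tot <- tot + (2 * n + 1) / n * f^(n - 1) * (n * pr * Pn + pt * Qn)
  }
  tot / (4 * pi * sigma * a^2)
}

# a hand-built chain adjacency over n nodes
chain_adjacency <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    sort(c(if (i > 1) i - 1, if (i < n) i + 1)))
  structure(list(n = n, neighbors = nb, labels = as.character(seq_len(n))),
            class = "adjacency_graph")
}

# complex white-noise "trials" seen through a dipole topography, as
# channel x trial coefficient matrices (for CSD/beamformer tests)
dipole_trials <- function(lf_col, n_trials, noise_sd, amp = 1) {
  nch <- length(lf_col)
  vapply(seq_len(n_trials), function(i)
    amp * (rnorm(1) + 1i * rnorm(1)) / sqrt(2) * lf_col +
      (rnorm(nch) + 1i * rnorm(nch)) / sqrt(2) * noise_sd,
    complex(nch))
}
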