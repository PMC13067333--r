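fs <- 250

random_phase_tfr <- function(n_trials, nch = 1, nf = 2, nt = 201, seed = 1) {
  set.seed(seed)
  coef <- lapply(seq_len(n_trials), function(i)
    array(complex(modulus = 1, argument = runif(nch * nf * nt, -pi, pi)),
          dim = c(nch, nf, nt)))
  make_tfr(coef, fs, 20, c(2, 8))
}

test_that("identical trials give ITPC exactly 1", {
  set.seed(7)
  one <- array(complex(real = rnorm(2 * 2 * 101), imaginary = rnorm(404)),
               dim = c(2, 2, 101))
  tfr <- make_tfr(rep(list(one), 20), fs, 20, c(2, 8))
  it <- itpc_binned(tfr, list(win = c(-300, 300), event = "disappear"))
  expect_equal(max(abs(it$values - 1)), 0, tolerance = 1e-12)
})

test_that("uniform random phases give the Rayleigh resultant expectation", {
  for (N in c(20, 470)) {
    tfr <- random_phase_tfr(N, nf = 2, nt = 401, seed = N)
    it <- itpc_binned(tfr, list(win = c(-1500, 1500), event = "disappear"))
    expected <- sqrt(pi) / (2 * sqrt(N))
    # mean over many independent cells; SE from the Rayleigh variance
    m <- mean(it$values)
    se <- sqrt((4 - pi) / (4 * N) / (2 * 150)) # cells = freqs x samples
    expect_lt(abs(m - expected), 4 * se + 0.002)
  }
})

test_that("ITPC is invariant to common phase rotation and trial order", {
  tfr <- random_phase_tfr(12, seed = 3)
  it <- itpc_binned(tfr, list(win = c(-300, 300), event = "disappear"))
  rot <- tfr
  rot$coef <- lapply(rot$coef, function(a) a * exp(1.234i))
  itr <- itpc_binned(rot, list(win = c(-300, 300), event = "disappear"))
  expect_equal(itr$values, it$values, tolerance = 1e-12)
  shuf <- tfr
  shuf$coef <- shuf$coef[sample(12)]
  its <- itpc_binned(shuf, list(win = c(-300, 300), event = "disappear"))
  expect_equal(its$values, it$values, tolerance = 1e-12)
  # bounded in [0, 1]
  expect_true(all(it$values >= 0 & it$values <= 1))
  # magnitude has no influence: scaling one trial leaves ITPC unchanged
  sc <- tfr
  sc$coef[[1]] <- sc$coef[[1]] * 50
  expect_equal(itpc_binned(sc, list(win = c(-300, 300),
                                    event = "disappear"))$values,
               it$values, tolerance = 1e-12)
})

test_that("a phase-locked delta generator shows disappearance-locked ITPC above surrogate", {
  d <- task_design(sampling_rate_hz = 200)
  lay <- sensor_layout(8)
  sch <- suppressWarnings(build_schedule(d, 40, 5))
  rec <- simulate_eeg(sch, oscillatory_truth(delta_kappa = 8, snr = 2),
                      lay, d, seed = 6)
  ep <- epoch_recording(rec, d)
  bank <- build_bank(0.5, 8, 6, 2, 4, fs = 200)
  tfr <- tfr_convolve(ep, bank, 25)
  it <- itpc_binned(tfr, "disappearance")
  obs <- max(band_window_average(it, c(0.5, 4), c(-100, 900),
                                 use_valid = FALSE))
  # surrogate: phase-scramble trials by rotating each trial's phases
  set.seed(2)
  null <- replicate(30, {
    sur <- tfr
    # destroy time-locking by permuting each trial's time axis
    sur$coef <- lapply(sur$coef, function(a)
      a[, , sample(dim(a)[3]), drop = FALSE])
    max(band_window_average(
      itpc_binned(sur, "disappearance"), c(0.5, 4), c(-100, 900),
      use_valid = FALSE))
  })
  expect_gt(obs, quantile(null, 0.99))
  # no injected locking: kappa = 0 stays within the surrogate distribution
  rec0 <- simulate_eeg(sch, oscillatory_truth(delta_kappa = 0, snr = 2),
                       lay, d, seed = 7)
  tfr0 <- tfr_convolve(epoch_recording(rec0, d), bank, 25)
  obs0 <- max(band_window_average(itpc_binned(tfr0, "disappearance"),
                                  c(0.5, 4), c(-100, 900), use_valid = FALSE))
  expect_lt(obs0, obs)
  expect_lt(obs0, quantile(null, 0.99) * 2.5)
})
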