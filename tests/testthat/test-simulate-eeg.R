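test_that("snr 0 yields pure background with the requested spectral slope", {
  d <- task_design(sampling_rate_hz = 250)
  sch <- suppressWarnings(build_schedule(d, 6, 2))
  lay <- sensor_layout(4)
  for (expo in c(0.5, 1, 1.5)) {
    rec <- simulate_eeg(sch, oscillatory_truth(noise_exponent = expo, snr = 0),
                        lay, d, seed = 3)
    sp <- stats::spec.pgram(rec$signal[1, ], spans = 25, plot = FALSE,
                            taper = 0, detrend = TRUE)
    keep <- sp$freq * 250 >= 2 & sp$freq * 250 <= 60
    slope <- -coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
    expect_lt(abs(slope - expo), 0.2)
  }
  # identical seeds give bit-identical recordings
  r1 <- simulate_eeg(sch, oscillatory_truth(), lay, d, seed = 5)
  r2 <- simulate_eeg(sch, oscillatory_truth(), lay, d, seed = 5)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$markers, r2$markers)
  r3 <- simulate_eeg(sch, oscillatory_truth(), lay, d, seed = 6)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("markers are sorted, complete and inside the recording", {
  d <- task_design(sampling_rate_hz = 200)
  sch <- suppressWarnings(build_schedule(d, 5, 9))
  rec <- simulate_eeg(sch, oscillatory_truth(snr = 0), sensor_layout(4), d,
                      seed = 1)
  expect_equal(nrow(rec$markers), 20) # 4 events x 5 trials
  expect_true(!is.unsorted(rec$markers$sample))
  expect_true(all(rec$markers$sample >= 1 &
                    rec$markers$sample <= ncol(rec$signal)))
  expect_equal(sum(rec$markers$label == "disappear"), 5)
  expect_error(simulate_eeg(sch, oscillatory_truth(
    beta_loc_mm = c(0, 0, 200)), sensor_layout(4), d), "outside")
})

test_that("beta suppression shows as negative normalized power over the generator", {
  d <- task_design(sampling_rate_hz = 200)
  lay <- sensor_layout(16)
  sch <- suppressWarnings(build_schedule(d, 30, 4))
  tr <- oscillatory_truth(beta_suppression = -0.4, delta_kappa = 0, snr = 2)
  rec <- simulate_eeg(sch, tr, lay, d, seed = 8)
  ep <- epoch_recording(rec, d)
  tfr <- tfr_convolve(ep, build_bank(4, 35, 8, fs = 200), 20)
  bl <- power_binned(tfr, "norm_baseline")
  dm <- baseline_normalize(power_binned(tfr, "disappearance"), bl, "relative")
  beta_chan <- band_window_average(dm, c(13, 30), c(-200, 600),
                                   use_valid = FALSE)
  topo <- abs(dipole_topography(head_model(), lay, tr$beta_loc_mm,
                                tpeeg:::.tangential_orientation(tr$beta_loc_mm)))
  over <- order(-topo)[1:3]
  expect_lt(mean(beta_chan[over]), -0.15)
  # and the suppression is ordered: stronger injected drop, more negative
  tr2 <- oscillatory_truth(beta_suppression = -0.1, delta_kappa = 0, snr = 2)
  rec2 <- simulate_eeg(sch, tr2, lay, d, seed = 8)
  tfr2 <- tfr_convolve(epoch_recording(rec2, d), build_bank(4, 35, 8, fs = 200), 20)
  dm2 <- baseline_normalize(power_binned(tfr2, "disappearance"),
                            power_binned(tfr2, "norm_baseline"), "relative")
  beta2 <- band_window_average(dm2, c(13, 30), c(-200, 600),
                               use_valid = FALSE)
  expect_lt(mean(beta_chan[over]), mean(beta2[over]))
})

test_that("the optional stimulator comb is removed by the filter chain", {
  d <- task_design(sampling_rate_hz = 1000)
  sch <- suppressWarnings(build_schedule(d, 2, 2))
  lay <- sensor_layout(2)
  rec <- simulate_eeg(sch, oscillatory_truth(snr = 0, dbs_freq_hz = 130),
                      lay, d, seed = 4)
  flt <- filter_continuous(rec, filter_spec())
  spec_at <- function(x, f0) {
    sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
    mean(sp$spec[abs(sp$freq * 1000 - f0) < 2])
  }
  core <- seq(2000, ncol(rec$signal) - 2000)
  # the 130 Hz fundamental sits above the 95 Hz low-pass
  expect_lt(spec_at(flt$signal[1, core], 130),
            spec_at(rec$signal[1, core], 130) / 100)
})
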