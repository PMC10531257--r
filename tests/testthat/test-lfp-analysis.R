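test_that("low-pass filter meets its frequency-response contract", {
  fs <- 9000
  t <- (0:(fs * 2 - 1)) / fs
  steady <- fs:(2 * fs)   # second half: transient has decayed

  dc <- lowpass_filter(trace_recording(rep(100, fs), fs, filtered = FALSE))
  expect_lt(abs(dc$signal[1, 1, fs] - 100), 0.5)

  f200 <- lowpass_filter(trace_recording(100 * sin(2 * pi * 200 * t), fs,
                                         filtered = FALSE), 200, 5)
  gain <- max(abs(f200$signal[1, 1, steady])) / 100
  expect_gt(gain, 0.66)
  expect_lt(gain, 0.75)

  f1k <- lowpass_filter(trace_recording(100 * sin(2 * pi * 1000 * t), fs,
                                        filtered = FALSE), 200, 5)
  atten_db <- -20 * log10(max(abs(f1k$signal[1, 1, steady])) / 100)
  expect_gte(atten_db, 30)

  expect_error(lowpass_filter(dc, cutoff_hz = 5000), "Nyquist")
  expect_true(f200$filtered)
})

test_that("noise energy is the median windowed energy", {
  fs <- 9000
  expect_equal(estimate_noise_energy(numeric(fs), fs), 0)
  set.seed(8)
  x <- rnorm(fs * 2, 0, 10)
  ne <- estimate_noise_energy(x, fs)
  expect_lt(abs(ne - 100) / 100, 0.10)

  # one large event in < 50% of windows barely moves the median
  xe <- x
  xe[2000:4000] <- xe[2000:4000] + 500
  expect_lt(abs(estimate_noise_energy(xe, fs) - ne) / ne, 0.05)

  expect_error(estimate_noise_energy(rnorm(100), fs), "10 windows")
})

test_that("double-threshold detection finds planted pulses", {
  fs <- 9000
  expect_equal(nrow(detect_lfp_events(constant_recording(0, nt = fs * 2,
                                                         filtered = TRUE))),
               0)

  x <- numeric(fs * 2)
  x[9000:9090] <- triangular_pulse(60, 46, 45)
  ev <- detect_lfp_events(trace_recording(x, fs), lfp_params())
  e1 <- ev[ev$row == 0 & ev$col == 0, ]
  expect_equal(nrow(e1), 1)
  expect_equal(e1$amplitude_uv, 60)

  # two pulses 30 ms apart merge under the 50 ms refractory period
  x2 <- numeric(fs * 2)
  x2[9000:9045] <- triangular_pulse(60, 23, 23)
  x2[9000 + round(0.030 * fs) + 0:45] <- triangular_pulse(60, 23, 23)
  ev2 <- detect_lfp_events(trace_recording(x2, fs), lfp_params())
  expect_equal(nrow(ev2[ev2$row == 0 & ev2$col == 0, ]), 1)

  # sub-threshold signal: no events
  x3 <- numeric(fs * 2)
  x3[9000:9090] <- triangular_pulse(39.9, 46, 45)
  expect_equal(nrow(detect_lfp_events(trace_recording(x3, fs))), 0)

  expect_warning(detect_lfp_events(trace_recording(x, fs, filtered = FALSE)),
                 "not flagged")
})

test_that("detector matches the brute-force scan event-for-event", {
  fs <- 9000
  p <- lfp_params()
  set.seed(77)
  for (i in 1:150) {
    x <- random_lfp_trace(fs * 2, fs)
    ev <- detect_lfp_events(trace_recording(x, fs), p)
    got <- sort(ev$peak_time_s[ev$row == 0 & ev$col == 0])
    want <- (oracle_lfp_scan(x, p$upper_uv, p$lower_uv,
                             p$refractory_ms / 1000 * fs) - 1) / fs
    expect_equal(got, want)
  }
})

test_that("raising the thresholds never increases the event count", {
  fs <- 9000
  set.seed(55)
  x <- random_lfp_trace(fs * 2, fs)
  counts <- vapply(c(20, 40, 60, 90, 140), function(thr) {
    nrow(detect_lfp_events(trace_recording(x, fs),
                           lfp_params(upper_uv = thr, lower_uv = -thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("energy-walk duration recovers a square pulse", {
  fs <- 9000
  set.seed(12)
  x <- rnorm(fs * 4, 0, 1)          # near-zero noise floor
  x[18000:(18000 + 900 - 1)] <- 100 # 100 ms square pulse
  ne <- estimate_noise_energy(x, fs)
  d <- estimate_event_duration(x, 18450, fs, window_ms = 50,
                               energy_factor = 1.5, noise_energy = ne)
  expect_lt(abs(d$duration_ms - 100), 50)  # within one window width
  expect_false(d$truncated)

  # symmetric pulse: forward and backward extents agree
  xs <- rnorm(fs * 4, 0, 1)
  pk <- 18000
  xs[(pk - 450):(pk + 450)] <- xs[(pk - 450):(pk + 450)] +
    100 * exp(-((-450:450) / 150)^2)
  ds <- estimate_event_duration(xs, pk, fs, noise_energy =
                                  estimate_noise_energy(xs, fs))
  expect_lt(abs((ds$end_idx - pk) - (pk - ds$start_idx)), 0.01 * fs)

  # energy never above 1.5x noise: minimal one-window duration, flagged
  xq <- rnorm(fs * 4, 0, 10)
  dq <- estimate_event_duration(xq, 18000, fs, noise_energy =
                                  estimate_noise_energy(xq, fs))
  expect_equal(dq$duration_ms, 50)
  expect_true(dq$degenerate)
})

test_that("area-coincidence cleaning applies the 40% rule inclusively", {
  fs <- 9000
  g <- electrode_grid(4, 4)
  area10 <- area_masks(tibble::tibble(area = "DG",
                                      row = c(0, 0, 0, 0, 1, 1, 1, 1, 2, 2),
                                      col = c(0, 1, 2, 3, 0, 1, 2, 3, 0, 1)),
                       g)
  # build a recording with synchronized pulses on k electrodes of the area
  mk_events <- function(k) {
    sig <- array(0, c(4, 4, fs))
    at <- tibble::as_tibble(area10)[seq_len(k), ]
    for (i in seq_len(k)) {
      sig[at$row[i] + 1, at$col[i] + 1, 4500:4590] <- triangular_pulse(80, 46, 45)
    }
    rec <- mea_recording(sig, fs, g, filtered = TRUE)
    detect_lfp_events(rec, lfp_params(active_rate_min = 0))
  }
  ev4 <- clean_events_by_area(mk_events(4), area10)
  expect_true(all(ev4$valid))       # 4 of 10 = 40%, inclusive boundary
  ev3 <- clean_events_by_area(mk_events(3), area10)
  expect_false(any(ev3$valid))      # 3 of 10 < 40%

  # single-electrode area: one event is trivially valid (1 >= 0.4)
  g1 <- electrode_grid(2, 2)
  sig <- array(0, c(2, 2, fs))
  sig[1, 1, 4500:4590] <- triangular_pulse(80, 46, 45)
  ev1 <- detect_lfp_events(mea_recording(sig, fs, g1, filtered = TRUE),
                           lfp_params(active_rate_min = 0))
  a1 <- area_masks(tibble::tibble(area = "CA1", row = 0L, col = 0L), g1)
  ev1c <- clean_events_by_area(ev1, a1)
  expect_true(all(ev1c$valid[ev1c$area == "CA1"]))

  # events on electrodes outside every area are dropped with a message
  sig2 <- sig
  sig2[2, 2, 4500:4590] <- triangular_pulse(80, 46, 45)
  evb <- detect_lfp_events(mea_recording(sig2, fs, g1, filtered = TRUE),
                           lfp_params(active_rate_min = 0))
  expect_message(evbc <- clean_events_by_area(evb, a1), "outside")
  expect_true(all(evbc$area == "CA1"))
})

test_that("feature table averages valid events on active electrodes", {
  fs <- 3000
  g <- electrode_grid(2, 2)
  sig <- array(0, c(2, 2, fs * 60))
  for (k in 0:5) {   # 6 events in 60 s -> 6 events/min, rate 0.1/s active
    at <- k * 10 * fs + fs
    sig[1, 1, at:(at + 135)] <- triangular_pulse(300, 68, 68)
  }
  rec <- mea_recording(sig, fs, g, filtered = TRUE)
  ev <- detect_lfp_events(rec, lfp_params())
  ft <- lfp_feature_table(ev)
  expect_true(ft$any_valid)
  expect_equal(ft$n_active_sites, 1L)
  expect_equal(ft$electrodes$rate_per_min, 6)
  expect_lt(abs(abs(ft$electrodes$mean_amplitude_uv) - 300), 1)

  ft0 <- lfp_feature_table(detect_lfp_events(
    constant_recording(0, nt = fs, fs = fs, filtered = TRUE)))
  expect_false(ft0$any_valid)
  expect_equal(ft0$n_active_sites, 0L)
})

test_that("planted event rate is recovered exactly without noise", {
  g <- electrode_grid(7, 7)
  onsets <- seq(1, 19, by = 2)   # 10 events in 20 s
  w <- lfp_wave_config(c(3, 3), peak_amplitude = 300, onset_times = onsets)
  cfg0 <- spike_gen_config(base_rate = 0, noise_sd = 0, seed = 2)
  emp <- spike_trains(tibble::tibble(), 20, g)
  rec0 <- synthesize_recording(emp, list(w), cfg0, g,
                               sampling_rate = 3000)$recording
  ev0 <- detect_lfp_events(lowpass_filter(rec0), lfp_params())
  ctr0 <- ev0[ev0$row == 3 & ev0$col == 3, ]
  expect_equal(nrow(ctr0), length(onsets))

  # SNR 5 (300 uV peak over 60 uV generator noise): the recovered rate --
  # planted events matched by a detection on the same electrode within
  # +/- 50 ms -- stays within 10% of the planted rate
  cfg5 <- spike_gen_config(base_rate = 0, noise_sd = 60, seed = 2)
  rec5 <- synthesize_recording(emp, list(w), cfg5, g,
                               sampling_rate = 3000)$recording
  ev5 <- detect_lfp_events(lowpass_filter(rec5), lfp_params())
  ctr5 <- ev5[ev5$row == 3 & ev5$col == 3, ]
  matched <- vapply(onsets, function(o)
    any(abs(ctr5$peak_time_s - o) < 0.05 + 0.05), logical(1))
  expect_lte(abs(sum(matched) - length(onsets)) / length(onsets), 0.1)
})
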