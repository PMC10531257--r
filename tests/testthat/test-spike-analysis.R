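test_that("spike detector finds planted biphasic spikes and ignores noise", {
  expect_equal(nrow(detect_spikes(constant_recording(0, nt = 9000))), 0)

  # planted spikes at SNR 10 on one electrode
  fs <- 9000
  set.seed(31)
  n <- fs * 10
  true_t <- sort(runif(80, 0.1, 9.9))
  g <- electrode_grid(2, 2)
  cfg <- spike_gen_config(base_rate = 0, spike_waveform_amplitude = 100,
                          noise_sd = 10, seed = 31)
  tr <- spike_trains(tibble::tibble(row = 0L, col = 0L, time_s = true_t),
                     10, g)
  rec <- synthesize_recording(tr, list(), cfg, g, sampling_rate = fs)$recording
  det <- detect_spikes(rec, sd_factor = 5)
  det1 <- det[det$row == 0 & det$col == 0, ]
  # match detections to truth within +/- 1 ms
  hits <- vapply(true_t, function(t0) any(abs(det1$time_s - t0) <= 0.0015),
                 logical(1))
  recall <- mean(hits)
  precision <- mean(vapply(det1$time_s, function(t0)
    any(abs(true_t - t0) <= 0.0015), logical(1)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  expect_error(detect_spikes(rec, dead_time_ms = 0), "dead_time")
})

test_that("dead time keeps one of two close extrema", {
  fs <- 9000
  x <- rnorm(fs, 0, 2)
  x[1000] <- -100
  x[1000 + round(0.0005 * fs)] <- -100   # second extremum 0.5 ms later
  rec <- trace_recording(x, fs, filtered = FALSE)
  det <- detect_spikes(rec, sd_factor = 5, dead_time_ms = 1)
  d1 <- det[det$row == 0 & det$col == 0, ]
  expect_equal(sum(abs(d1$time_s - 1000 / fs) < 0.002), 1)
})

test_that("spike statistics are exact arithmetic", {
  g <- electrode_grid(2, 2)
  even <- spike_trains(tibble::tibble(row = 0L, col = 0L,
                                      time_s = seq(0.5, 59.5, by = 1)),
                       60, g)
  st <- spike_statistics(even)
  expect_equal(st$nos, 60L)
  expect_equal(st$mfr, 1.0)
  expect_equal(st$mean_isi_ms, 1000)

  empty <- spike_trains(tibble::tibble(), 60, g)
  expect_equal(nrow(spike_statistics(empty)), 0)

  tri <- spike_trains(tibble::tibble(row = 0L, col = 0L,
                                     time_s = c(0, 0.1, 0.4)), 1, g)
  st3 <- spike_statistics(tri)
  expect_equal(st3$mean_isi_ms, 200)
  # single-spike electrode: ISI undefined, excluded from pooling
  one <- spike_trains(tibble::tibble(row = c(0L, 1L), col = c(0L, 0L),
                                     time_s = c(0.5, 0.1)), 1, g)
  # only spikes on two electrodes, one each -> both ISIs NA
  expect_true(all(is.na(spike_statistics(one)$mean_isi_ms)))
})

test_that("max-ISI burst detection matches the stated rule", {
  g <- electrode_grid(2, 2)
  t5 <- 0.5 + (0:4) * 0.010
  b <- detect_bursts(spike_trains(tibble::tibble(row = 0L, col = 0L,
                                                 time_s = t5), 2, g),
                     max_isi_ms = 100, min_spikes = 5)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 5L)
  expect_equal((b$end_s - b$start_s) * 1000, 40)

  b4 <- detect_bursts(spike_trains(tibble::tibble(row = 0L, col = 0L,
                                                  time_s = t5[1:4]), 2, g),
                      max_isi_ms = 100, min_spikes = 5)
  expect_equal(nrow(b4), 0)

  # gaps 10,10,200,10,10 ms: two runs of 3 spikes
  tt <- 0.1 + cumsum(c(0, 10, 10, 200, 10, 10)) / 1000
  b2 <- detect_bursts(spike_trains(tibble::tibble(row = 0L, col = 0L,
                                                  time_s = tt), 2, g),
                      max_isi_ms = 100, min_spikes = 3)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$n_spikes, c(3L, 3L))
})

test_that("burst detection agrees with exhaustive run enumeration", {
  g <- electrode_grid(2, 2)
  set.seed(99)
  for (i in 1:300) {
    n <- sample(0:50, 1)
    t <- sort(runif(n, 0, 5))
    max_isi <- runif(1, 0.02, 0.3)
    min_sp <- sample(2:6, 1)
    got <- detect_bursts(
      spike_trains(tibble::tibble(row = integer(n), col = integer(n),
                                  time_s = t), 5, g),
      max_isi_ms = max_isi * 1000, min_spikes = min_sp)
    want <- oracle_burst_runs(t, max_isi, min_sp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, want$start)
      expect_equal(got$end_s, want$end)
      expect_equal(got$n_spikes, as.integer(want$n))
    }
  }
})

test_that("burst statistics summarize and flag the empty case", {
  g <- electrode_grid(2, 2)
  t5 <- 0.5 + (0:4) * 0.010
  b <- detect_bursts(spike_trains(tibble::tibble(row = 0L, col = 0L,
                                                 time_s = t5), 60, g),
                     min_spikes = 5)
  s <- burst_statistics(b)
  expect_equal(s$mean_duration_ms, 40)
  expect_equal(s$mean_spikes_per_burst, 5)
  expect_equal(s$burst_rate_per_min, 1)

  s0 <- burst_statistics(detect_bursts(spike_trains(tibble::tibble(), 60, g)))
  expect_false(s0$any_bursts)
  expect_true(is.na(s0$mean_duration_ms))
})

test_that("network bursts require the participation fraction", {
  g <- electrode_grid(4, 4)
  # all 16 electrodes burst together for ~500 ms
  all_b <- tidyr::expand_grid(row = 0:3, col = 0:3) |>
    dplyr::mutate(spk = list(seq(1.0, 1.5, by = 0.02))) |>
    tidyr::unnest(spk) |>
    dplyr::rename(time_s = spk)
  tr <- spike_trains(all_b, 3, g)
  b <- detect_bursts(tr, max_isi_ms = 100, min_spikes = 5)
  nb <- detect_network_bursts(b, bin_ms = 10, participation_fraction = 0.2)
  expect_equal(nrow(nb), 1)
  expect_lt(abs(nb$duration_ms - 500), 25)

  empty <- detect_network_bursts(detect_bursts(spike_trains(tibble::tibble(),
                                                            3, g)))
  expect_equal(nrow(empty), 0)

  # staggered bursts on 30% of electrodes never reach a 0.5 threshold
  stag <- purrr::map_dfr(0:9, function(k) {
    tibble::tibble(row = k %/% 4, col = k %% 4,
                   time_s = k * 0.6 + seq(0, 0.1, by = 0.02))
  })
  trs <- spike_trains(stag, 7, g)
  bs <- detect_bursts(trs, max_isi_ms = 100, min_spikes = 5)
  nbs <- detect_network_bursts(bs, bin_ms = 10, participation_fraction = 0.5,
                               n_active = 10)
  expect_equal(nrow(nbs), 0)
})

test_that("activity map conserves total spike count", {
  g <- electrode_grid(3, 3)
  tr <- spike_trains(tibble::tibble(row = c(0L, 0L, 2L), col = c(0L, 0L, 1L),
                                    time_s = c(0.1, 0.4, 0.9)), 2, g)
  st <- spike_statistics(tr)
  m <- activity_map(st, g)
  expect_equal(sum(m != 0), 2)
  expect_equal(sum(m) * 2, 3)   # map sum x duration = total NOS
})
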