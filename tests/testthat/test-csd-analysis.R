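test_that("inpainting reproduces constants and planes exactly", {
  g <- electrode_grid(8, 8)
  sig <- array(10, c(8, 8, 3))
  rec <- mea_recording(sig, 9000, g)
  m0 <- detect_saturation(rec, 4000)
  expect_identical(inpaint_saturated(rec, m0)$signal, sig)  # nothing to do

  sig[4, 4, 2] <- 9999
  rec <- mea_recording(sig, 9000, g)
  ip <- inpaint_saturated(rec, detect_saturation(rec, 5000))
  expect_equal(ip$signal[4, 4, 2], 10, tolerance = 1e-6)

  plane <- outer(0:7, 0:7, function(r, c) 3 * r - 2 * c + 5)
  sigp <- array(plane, c(8, 8, 2))
  sigp[4, 5, 1] <- 1e5
  recp <- mea_recording(sigp, 9000, g)
  ipp <- inpaint_saturated(recp, detect_saturation(recp, 5e4))
  expect_equal(ipp$signal[4, 5, 1], plane[4, 5], tolerance = 1e-6)

  # a frame saturated beyond the guard refuses to inpaint
  sigf <- array(9999, c(8, 8, 1))
  recf <- mea_recording(sigf, 9000, g)
  expect_error(inpaint_saturated(recf, detect_saturation(recf, 5000)),
               "saturated")
})

test_that("spatial smoothing preserves constants and composes", {
  g <- electrode_grid(10, 10)
  cst <- make_analytic_field("uniform", list(value = 7), g, n_samples = 2)
  expect_equal(max(abs(smooth_spatial(cst, 1)$signal - 7)), 0,
               tolerance = 1e-12)

  # delta response: center value equals the discrete kernel center weight
  dl <- make_analytic_field("delta", list(at = c(5, 5)), g)
  sm <- smooth_spatial(dl, 1)
  half <- 3L
  w <- exp(-(-half:half)^2 / 2)
  expect_equal(sm$signal[6, 6, 1], (w[half + 1] / sum(w))^2,
               tolerance = 1e-12)

  # semigroup: sigma then sigma ~ sigma * sqrt(2), away from boundaries
  set.seed(44)
  fld <- mea_recording(array(rnorm(100 * 3), c(10, 10, 3)), 9000, g)
  twice <- smooth_spatial(smooth_spatial(fld, 0.8), 0.8)
  once <- smooth_spatial(fld, 0.8 * sqrt(2))
  i <- 4:7
  expect_equal(twice$signal[i, i, ], once$signal[i, i, ], tolerance = 0.02)
})

test_that("the 9-point stencil has its analytic responses", {
  g <- electrode_grid(10, 10)
  u <- compute_csd(make_analytic_field("uniform", list(value = 3), g))
  expect_equal(max(abs(u$csd[2:9, 2:9, 1])), 0)
  expect_true(all(is.na(u$csd[1, , 1])))   # boundary invalid

  d <- compute_csd(make_analytic_field("delta", list(at = c(5, 5)), g))
  expect_equal(d$csd[6, 6, 1], 10 / 3, tolerance = 1e-12)

  # sinusoid: CSD ~ (kx^2 + ky^2) phi within 2% at k = 0.2, error
  # decreasing with k
  errs <- vapply(c(0.4, 0.2, 0.1), function(k) {
    gg <- electrode_grid(32, 32)
    f <- make_analytic_field("sinusoid", list(kx = k, ky = k), gg)
    cv <- compute_csd(f)
    pred <- 2 * k^2 * f$signal[, , 1]
    i <- 2:31
    max(abs(cv$csd[i, i, 1] - pred[i, i])) / max(abs(pred[i, i]))
  }, numeric(1))
  expect_lt(errs[2], 0.02)
  expect_true(all(diff(errs) < 0))

  expect_error(compute_csd(make_analytic_field("uniform", list(value = 1),
                                               electrode_grid(2, 2))),
               "3 x 3")
})

test_that("CSD is linear and conserves compactly supported fields", {
  g <- electrode_grid(12, 12)
  set.seed(9)
  mk <- function() {
    m <- matrix(0, 12, 12)
    m[4:9, 4:9] <- rnorm(36)
    mea_recording(array(m, c(12, 12, 1)), 9000, g, filtered = TRUE)
  }
  f1 <- mk(); f2 <- mk()
  c1 <- compute_csd(f1)$csd; c2 <- compute_csd(f2)$csd
  comb <- f1
  comb$signal <- 2.5 * f1$signal - 1.25 * f2$signal
  cc <- compute_csd(comb)$csd
  i <- 2:11
  expect_equal(cc[i, i, ], 2.5 * c1[i, i, ] - 1.25 * c2[i, i, ],
               tolerance = 1e-12)

  # interior sum telescopes to zero for fields vanishing near the boundary
  s <- sum(c1[i, i, 1])
  expect_lt(abs(s) / max(abs(c1[i, i, 1])), 1e-6)
})

test_that("Hilbert envelope tracks pure and modulated tones", {
  fs <- 9000
  t <- (0:(fs * 2 - 1)) / fs
  tone <- trace_recording(50 * sin(2 * pi * 10 * t), fs)
  A <- hilbert_amplitude(tone)
  inner <- 2000:16000
  expect_lt(max(abs(A$amplitude[1, 1, inner] - 50)) / 50, 0.02)

  z <- hilbert_amplitude(constant_recording(0, nt = 100, filtered = TRUE))
  expect_equal(max(z$amplitude), 0)
  expect_equal(max(z$variability), 0)

  am <- 1 + 0.5 * sin(2 * pi * 1 * t)
  rec <- trace_recording(40 * am * sin(2 * pi * 30 * t), fs)
  Am <- hilbert_amplitude(rec)
  expect_lt(max(abs(Am$amplitude[1, 1, inner] - 40 * am[inner])) / 40, 0.05)
})

test_that("ROI selection applies the strict median + 2.326 SD rule", {
  g <- electrode_grid(64, 64)
  # constant variability: threshold equals xi, strict inequality -> empty
  fs <- 1000
  t <- (0:199) / fs
  sig <- array(rep(30 * sin(2 * pi * 25 * t), each = 64 * 64),
               c(64, 64, 200))
  A <- hilbert_amplitude(mea_recording(sig, fs, g, filtered = TRUE))
  m <- select_roi(A)
  expect_true(m$empty)

  # one high-variability electrode among 4096
  sig2 <- array(rep(sin(2 * pi * 25 * t), each = 64 * 64), c(64, 64, 200))
  sig2[11, 11, ] <- 100 * sin(2 * pi * 25 * t) * sin(2 * pi * 2 * t)
  A2 <- hilbert_amplitude(mea_recording(sig2, fs, g, filtered = TRUE))
  m2 <- select_roi(A2)
  expect_equal(which(m2$roi, arr.ind = TRUE)[1, ], c(row = 11, col = 11))
  expect_equal(sum(m2$roi), 1)
})

test_that("TOI thresholds against the non-ROI noise statistics", {
  g <- electrode_grid(6, 6)
  fs <- 1000
  nt <- 2000
  set.seed(13)
  # heterogeneous per-electrode noise (gain spread), so the inter-electrode
  # amplitude spread that the TOI threshold keys on is non-degenerate
  sds <- matrix(runif(36, 4, 8), 6, 6)
  sds[4, 4] <- 3   # the probed electrodes sit at the quiet end of the
  sds[2, 2] <- 3   # gain spread, so their baseline stays below threshold
  sig <- array(rnorm(6 * 6 * nt), c(6, 6, nt)) *
    array(sds, c(6, 6, nt))
  # ROI electrode (3,3): quiet except a strong 200 ms tone burst
  burst <- 801:1000
  sig[4, 4, burst] <- sig[4, 4, burst] + 200 * sin(2 * pi * 50 * (1:200) / fs)
  rec <- mea_recording(sig, fs, g, filtered = TRUE)
  A <- hilbert_amplitude(rec)
  mask <- select_roi(A)
  expect_false(mask$empty)
  expect_true(mask$roi[4, 4])
  mask <- select_toi(A, mask)
  toi <- mask$toi[4, 4, ]
  # the burst is covered and quiet time mostly excluded
  expect_gt(mean(toi[burst]), 0.9)
  expect_lt(mean(toi[-burst]), 0.1)
  # noise statistics describe the complement's mean amplitude
  abar <- A$mean_amplitude[!mask$roi]
  expect_equal(mask$mu_noise, mean(abar))
  expect_equal(mask$sigma_noise, sd(abar))

  # ROI electrode carrying only noise: essentially no TOI samples
  mask2 <- mask
  mask2$roi[,] <- FALSE; mask2$roi[2, 2] <- TRUE; mask2$empty <- FALSE
  mask2 <- select_toi(A, mask2)
  expect_lt(mean(mask2$toi[2, 2, ]), 0.01)

  # degenerate masks raise
  em <- mask; em$roi[,] <- FALSE; em$empty <- TRUE
  expect_error(select_toi(A, em), "empty")
  fl <- mask; fl$roi[,] <- TRUE; fl$empty <- FALSE
  expect_error(select_toi(A, fl), "complement")
})

test_that("rectified CSD equals the brute-force masked mean", {
  g <- electrode_grid(8, 8)
  nt <- 50
  set.seed(17)
  sig <- array(rnorm(8 * 8 * nt, 0, 20), c(8, 8, nt))
  rec <- mea_recording(sig, 1000, g, filtered = TRUE)
  cv <- compute_csd(smooth_spatial(rec, 1))
  mask <- structure(list(
    roi = matrix(FALSE, 8, 8), toi = array(FALSE, c(8, 8, nt)),
    empty = FALSE), class = "roi_toi")
  mask$roi[3:5, 3:5] <- TRUE
  mask$toi[3:5, 3:5, 10:30] <- TRUE
  got <- rectified_csd(cv, mask)
  acc <- c()
  for (r in 3:5) for (cc2 in 3:5) for (tt in 10:30) {
    acc <- c(acc, abs(cv$csd[r, cc2, tt]))
  }
  expect_equal(got, mean(acc))

  empty_mask <- mask
  empty_mask$toi[,,] <- FALSE
  expect_warning(r0 <- rectified_csd(cv, empty_mask), "empty")
  expect_true(is.na(r0))
})

test_that("sink/source decomposition partitions every frame", {
  g <- electrode_grid(16, 16)
  dp <- make_analytic_field("dipole",
                            list(sigma = 1.2, amplitude = 80, f_hz = 5,
                                 center_source = c(8, 4),
                                 center_sink = c(8, 11)),
                            g, n_samples = 100, sampling_rate = 1000)
  cv <- compute_csd(smooth_spatial(dp, 1))
  fr <- sink_source_frames(cv, c(0.05, 0.07))
  f1 <- fr$frames[[1]]
  i <- 2:15
  expect_identical(f1$sink[i, i] + f1$source[i, i], f1$signed[i, i])
  expect_true(all(f1$sink[i, i] <= 0))
  expect_true(all(f1$source[i, i] >= 0))
  # equal-integral dipole: sink and source magnitudes balance
  expect_lt(abs(sum(f1$sink[i, i]) + sum(f1$source[i, i])) /
              sum(f1$source[i, i]), 0.05)

  pos <- matrix(2, 16, 16)
  cvp <- compute_csd(mea_recording(array(pos, c(16, 16, 1)), 1000, g,
                                   filtered = TRUE))
  # uniform field: zero CSD, so both components vanish
  frp <- sink_source_frames(cvp, 0)$frames[[1]]
  expect_equal(sum(abs(frp$sink[i, i])), 0)

  expect_error(sink_source_frames(cv, 10), "outside")
})

test_that("stronger planted dipoles yield larger rCSD", {
  g <- electrode_grid(10, 10)
  rcsd_for <- function(ampl) {
    dp <- make_analytic_field("dipole",
                              list(sigma = 1.2, amplitude = ampl, f_hz = 5,
                                   center_source = c(5, 2),
                                   center_sink = c(5, 7)),
                              g, n_samples = 400, sampling_rate = 1000)
    # gate the oscillation on and off: amplitude *variability* (the ROI
    # statistic) responds to event-like envelopes, not steady tones
    gate <- as.numeric(seq_len(400) %in% 101:300)
    dp$signal <- dp$signal * rep(gate, each = 100)
    # weak noise so ROI selection is non-degenerate
    set.seed(23)
    dp$signal <- dp$signal + array(rnorm(length(dp$signal), 0, 0.5),
                                   dim = dim(dp$signal))
    A <- hilbert_amplitude(dp)
    m <- select_roi(A)
    m <- select_toi(A, m)
    rectified_csd(compute_csd(smooth_spatial(dp, 1)), m)
  }
  vals <- vapply(c(300, 600, 1200), rcsd_for, numeric(1))
  expect_true(all(diff(vals) > 0))
})
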