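#' Spike-train generator configuration
#'
#' Parameters of the synthetic activity model.  Each active electrode
#' carries an inhomogeneous Poisson spike train whose rate switches between
#' `base_rate` and `base_rate * burst_rate_multiplier` according to a
#' two-state continuous-time Markov modulator (the minimal model that
#' produces bursts and, when modulators align, network bursts).
#'
#' @param base_rate Baseline firing rate, spikes/s per electrode.
#' @param burst_rate_multiplier Rate multiplier in the burst ("on") state.
#' @param burst_on_rate,burst_off_rate Markov transition rates (per second)
#'   into and out of the burst state.
#' @param active_fraction Proportion of electrodes that fire at all.
#' @param spike_waveform_amplitude Peak spike amplitude in microvolts
#'   (negative-going biphasic waveform, ~1 ms).
#' @param noise_sd Additive white Gaussian noise SD in microvolts.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `spike_gen_config`.
#' @export
spike_gen_config <- function(base_rate = 2, burst_rate_multiplier = 10,
                             burst_on_rate = 0.05, burst_off_rate = 0.5,
                             active_fraction = 0.8,
                             spike_waveform_amplitude = 60,
                             noise_sd = 10, seed = 1L) {
  stopifnot(base_rate >= 0, burst_rate_multiplier >= 0,
            burst_on_rate >= 0, burst_off_rate >= 0,
            active_fraction >= 0, active_fraction <= 1,
            spike_waveform_amplitude >= 0, noise_sd >= 0)
  structure(list(base_rate = base_rate,
                 burst_rate_multiplier = burst_rate_multiplier,
                 burst_on_rate = burst_on_rate,
                 burst_off_rate = burst_off_rate,
                 active_fraction = active_fraction,
                 spike_waveform_amplitude = spike_waveform_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spike_gen_config")
}

#' Propagating LFP wave configuration
#'
#' A planted LFP event: a space--time separable deflection with Gaussian
#' spatial envelope that travels radially outward from `center` at
#' `propagation_speed`, with a double-exponential (rise/decay) time course.
#' The analytic peak amplitude, timing and spatial extent are known, so the
#' wave doubles as a detection and CSD oracle.
#'
#' @param center Electrode `(row, col)` at the wave origin (0-based).
#' @param peak_amplitude Peak deflection at the center electrode, uV (> 0).
#' @param rise_ms,decay_ms Time constants of the double-exponential kernel.
#' @param spatial_sigma Gaussian spatial extent, in electrode pitches (> 0).
#' @param propagation_speed Radial speed, electrodes per millisecond.
#' @param polarity `"sink-leading"` (negative deflection, the usual LFP
#'   sign) or `"source-leading"`.
#' @param onset_times Numeric vector of event onsets, seconds.
#' @return A list of class `lfp_wave_config`.
#' @export
lfp_wave_config <- function(center, peak_amplitude = 300,
                            rise_ms = 5, decay_ms = 20,
                            spatial_sigma = 1.5, propagation_speed = 0.5,
                            polarity = c("sink-leading", "source-leading"),
                            onset_times = numeric()) {
  polarity <- match.arg(polarity)
  stopifnot(length(center) == 2, peak_amplitude > 0, spatial_sigma > 0,
            rise_ms > 0, decay_ms > rise_ms, propagation_speed > 0)
  structure(list(center = as.numeric(center),
                 peak_amplitude = peak_amplitude,
                 rise_ms = rise_ms, decay_ms = decay_ms,
                 spatial_sigma = spatial_sigma,
                 propagation_speed = propagation_speed,
                 polarity = polarity,
                 onset_times = as.numeric(onset_times)),
            class = "lfp_wave_config")
}

# double-exponential kernel, unit peak; tau in ms (vectorized, 0 for tau < 0)
wave_kernel <- function(tau_ms, rise_ms, decay_ms) {
  tstar <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  norm <- exp(-tstar / decay_ms) - exp(-tstar / rise_ms)
  out <- (exp(-pmax(tau_ms, 0) / decay_ms) -
            exp(-pmax(tau_ms, 0) / rise_ms)) / norm
  out[tau_ms < 0] <- 0
  out
}

# kernel width (ms) above `level` of the peak, found numerically
wave_kernel_width <- function(rise_ms, decay_ms, level = 0.1) {
  tau <- seq(0, decay_ms * 12, by = 0.05)
  k <- wave_kernel(tau, rise_ms, decay_ms)
  diff(range(tau[k >= level]))
}

#' Construct a spike-train table
#'
#' @param x Tibble with columns `row`, `col`, `time_s` (0-based electrode
#'   coordinates, times in seconds).
#' @param duration Recording duration in seconds.
#' @param grid The [electrode_grid()] the trains live on.
#' @return `x` sorted by electrode and time, with class `spike_trains` and
#'   attributes `duration_s` and `grid`.
#' @export
spike_trains <- function(x, duration, grid) {
  stopifnot_grid(grid)
  stopifnot(duration > 0)
  x <- tibble::as_tibble(x)
  if (!nrow(x)) {
    x <- tibble::tibble(row = integer(), col = integer(), time_s = numeric())
  }
  x <- dplyr::arrange(x[, c("row", "col", "time_s")], row, col, time_s)
  if (nrow(x) && (any(x$time_s < 0) || any(x$time_s > duration))) {
    stop("spike times must lie in [0, duration]", call. = FALSE)
  }
  structure(x, class = c("spike_trains", class(tibble::tibble())),
            duration_s = as.numeric(duration), grid = grid)
}

train_duration <- function(spikes) attr(spikes, "duration_s")
train_grid <- function(spikes) attr(spikes, "grid")

#' Synthesize burst-modulated Poisson spike trains
#'
#' Draws, for each active electrode, a two-state Markov modulator (rates
#' `burst_on_rate` / `burst_off_rate`, initial state from the stationary
#' distribution) and an inhomogeneous Poisson train at `base_rate` in the
#' quiet state and `base_rate * burst_rate_multiplier` in the burst state.
#' All randomness flows from `cfg$seed`; the same seed reproduces the same
#' trains exactly.
#'
#' @param cfg A [spike_gen_config()].
#' @param duration Recording duration, seconds (> 0).
#' @param grid An [electrode_grid()].
#' @return A list with elements `spikes` (a [spike_trains()] tibble) and
#'   `ground_truth` (a [ground_truth()] holding the same spike times).
#' @export
synthesize_spike_trains <- function(cfg, duration, grid = electrode_grid()) {
  stopifnot(inherits(cfg, "spike_gen_config"), duration > 0)
  stopifnot_grid(grid)
  elec <- grid_electrodes(grid)
  n_active <- round(cfg$active_fraction * nrow(elec))
  sp <- withr::with_seed(cfg$seed, {
    idx <- if (n_active > 0) sample.int(nrow(elec), n_active) else integer()
    purrr::map_dfr(idx, function(i) {
      t <- simulate_modulated_train(cfg, duration)
      if (!length(t)) return(NULL)
      tibble::tibble(row = elec$row[i], col = elec$col[i], time_s = t)
    })
  })
  spikes <- spike_trains(sp, duration, grid)
  list(spikes = spikes,
       ground_truth = ground_truth(spikes = tibble::as_tibble(spikes)))
}

# one electrode's train under the two-state modulator; returns sorted times
simulate_modulated_train <- function(cfg, duration) {
  if (cfg$base_rate == 0) return(numeric())
  on_r <- cfg$burst_on_rate; off_r <- cfg$burst_off_rate
  if (cfg$burst_rate_multiplier == 1 || on_r == 0) {
    n <- stats::rpois(1, cfg$base_rate * duration)
    return(sort(stats::runif(n, 0, duration)))
  }
  p_on <- on_r / (on_r + off_r)
  state <- stats::runif(1) < p_on
  t0 <- 0
  times <- list()
  while (t0 < duration) {
    sojourn <- stats::rexp(1, if (state) off_r else on_r)
    t1 <- min(t0 + sojourn, duration)
    rate <- cfg$base_rate * if (state) cfg$burst_rate_multiplier else 1
    n <- stats::rpois(1, rate * (t1 - t0))
    if (n > 0) times[[length(times) + 1L]] <- stats::runif(n, t0, t1)
    t0 <- t1
    state <- !state
  }
  sort(unlist(times))
}

#' Render spikes, LFP waves and noise into a voltage recording
#'
#' The signal is the sum of three parts: a biphasic ~1 ms spike waveform
#' (one sine cycle, negative lobe first, peak `spike_waveform_amplitude`)
#' at every spike time; each configured LFP wave, rendered per electrode as
#' `peak_amplitude * exp(-d^2 / (2 sigma^2))` times the rise/decay kernel
#' delayed by `d / propagation_speed` (radial propagation); and white
#' Gaussian noise of SD `cfg$noise_sd`.  Everything planted is recorded in
#' the returned ground truth.
#'
#' @param spikes A [spike_trains()] table (may be empty).
#' @param waves List of [lfp_wave_config()] objects.
#' @param cfg A [spike_gen_config()] (amplitude, noise, seed).
#' @param grid An [electrode_grid()]; defaults to the spike trains' grid.
#' @param sampling_rate Sampling rate, Hz; must be at least 2000 to
#'   represent the spike waveform.
#' @param gt_min_amplitude_uv Planted LFP events are recorded per electrode
#'   in the ground-truth table only where the local envelope amplitude
#'   reaches this floor (keeps the table finite; default 40 uV, the LFP
#'   detection threshold magnitude).
#' @return A list with `recording` (an [mea_recording()]) and
#'   `ground_truth` (spike times, per-electrode planted LFP events, and the
#'   planted ROI: electrodes within half-maximum of any wave's envelope).
#' @export
synthesize_recording <- function(spikes, waves = list(), cfg,
                                 grid = train_grid(spikes),
                                 sampling_rate = 9000,
                                 gt_min_amplitude_uv = 40) {
  stopifnot(inherits(cfg, "spike_gen_config"))
  stopifnot_grid(grid)
  if (sampling_rate < 2000) {
    stop("sampling_rate below 2 kHz cannot represent the ~1 ms spike waveform",
         call. = FALSE)
  }
  duration <- train_duration(spikes)
  nt <- round(duration * sampling_rate)
  sig <- array(0, dim = c(grid$n_rows, grid$n_cols, nt))

  # biphasic spike waveform: one sine cycle of 1 ms, negative lobe first
  if (nrow(spikes) && cfg$spike_waveform_amplitude > 0) {
    wf_n <- max(round(0.001 * sampling_rate), 4L)
    wf <- -cfg$spike_waveform_amplitude * sin(2 * pi * seq_len(wf_n) / wf_n)
    for (k in seq_len(nrow(spikes))) {
      s0 <- round(spikes$time_s[k] * sampling_rate) + 1L
      idx <- s0:(s0 + wf_n - 1L)
      keep <- idx >= 1L & idx <= nt
      if (any(keep)) {
        r <- spikes$row[k] + 1L; cc <- spikes$col[k] + 1L
        sig[r, cc, idx[keep]] <- sig[r, cc, idx[keep]] + wf[keep]
      }
    }
  }

  gt_events <- list()
  roi <- NULL
  tgrid_ms <- (0:(nt - 1L)) / sampling_rate * 1000
  el <- grid_electrodes(grid)
  for (w in waves) {
    stopifnot(inherits(w, "lfp_wave_config"))
    d <- sqrt((el$row - w$center[1])^2 + (el$col - w$center[2])^2)
    amp <- w$peak_amplitude * exp(-d^2 / (2 * w$spatial_sigma^2))
    sgn <- if (w$polarity == "sink-leading") -1 else 1
    tstar_ms <- w$rise_ms * w$decay_ms / (w$decay_ms - w$rise_ms) *
      log(w$decay_ms / w$rise_ms)
    width_ms <- wave_kernel_width(w$rise_ms, w$decay_ms)
    keep <- amp >= min(gt_min_amplitude_uv, w$peak_amplitude)
    render <- amp >= 0.01 * w$peak_amplitude   # render well past the GT floor
    for (onset in w$onset_times) {
      for (i in which(render)) {
        tau <- tgrid_ms - (onset * 1000 + d[i] / w$propagation_speed)
        contrib <- sgn * amp[i] * wave_kernel(tau, w$rise_ms, w$decay_ms)
        sig[el$row[i] + 1L, el$col[i] + 1L, ] <-
          sig[el$row[i] + 1L, el$col[i] + 1L, ] + contrib
      }
      gt_events[[length(gt_events) + 1L]] <- tibble::tibble(
        row = el$row[keep], col = el$col[keep],
        onset_s = onset + d[keep] / w$propagation_speed / 1000,
        peak_time_s = onset + (d[keep] / w$propagation_speed + tstar_ms) / 1000,
        amplitude_uv = sgn * amp[keep],
        duration_ms = width_ms)
    }
    roi_w <- el[amp >= 0.5 * w$peak_amplitude, ]
    roi <- if (is.null(roi)) roi_w else dplyr::distinct(dplyr::bind_rows(roi, roi_w))
  }

  if (cfg$noise_sd > 0) {
    noise <- withr::with_seed(cfg$seed + 1L,
                              stats::rnorm(length(sig), 0, cfg$noise_sd))
    sig <- sig + array(noise, dim = dim(sig))
  }

  gt <- ground_truth(
    spikes = tibble::as_tibble(spikes),
    lfp_events = if (length(gt_events)) dplyr::bind_rows(gt_events) else NULL,
    roi = roi)
  rec <- mea_recording(sig, sampling_rate = sampling_rate, grid = grid)
  list(recording = rec, ground_truth = gt)
}

#' Condition presets for synthetic cohorts
#'
#' The `"hyper"` preset raises the baseline firing rate (x2.33), the burst
#' onset rate (x2) and the planted LFP event rate and amplitude (x3 and x2)
#' relative to `"control"`, emulating the direction of a hyperexcitable
#' culture/slice contrast.  Used for direction-of-effect tests only; the
#' factors are documented here, not fitted to anything.
#'
#' @param condition `"control"` or `"hyper"`.
#' @return Named list: `spike_cfg` (a [spike_gen_config()] without seed),
#'   `lfp_event_rate` (events/s), `lfp_peak_uv`.
#' @export
cohort_preset <- function(condition = c("control", "hyper")) {
  condition <- match.arg(condition)
  if (condition == "control") {
    list(base_rate = 1.5, burst_on_rate = 0.05,
         lfp_event_rate = 0.10, lfp_peak_uv = 150)
  } else {
    list(base_rate = 3.5, burst_on_rate = 0.10,
         lfp_event_rate = 0.30, lfp_peak_uv = 300)
  }
}

#' Synthesize a cohort of ground-truthed recordings
#'
#' Generates `n_recordings` independent recordings under a condition preset
#' (see [cohort_preset()]).  Each recording gets a seed derived stably from
#' `seed` and its index, so cohorts are reproducible and recordings
#' mutually independent.
#'
#' @param condition `"control"` or `"hyper"`.
#' @param n_recordings Number of recordings (>= 1).
#' @param seed Integer base seed.
#' @param grid Electrode grid (default 12 x 12 keeps cohorts desk-sized).
#' @param duration Seconds per recording.
#' @param sampling_rate Hz.
#' @return List of `n_recordings` elements, each a list with `recording`
#'   and `ground_truth`.
#' @export
synthesize_cohort <- function(condition = c("control", "hyper"),
                              n_recordings, seed = 1L,
                              grid = electrode_grid(12, 12),
                              duration = 30, sampling_rate = 3000) {
  condition <- match.arg(condition)
  if (!is.numeric(n_recordings) || n_recordings < 1) {
    stop("`n_recordings` must be >= 1", call. = FALSE)
  }
  purrr::map(seq_len(n_recordings), function(i)
    synthesize_cohort_recording(condition, i, seed = seed, grid = grid,
                                duration = duration,
                                sampling_rate = sampling_rate))
}

#' @rdname synthesize_cohort
#' @param index Recording index within the cohort (1-based); the
#'   per-recording seed derives stably from `seed`, `condition` and
#'   `index`, so single recordings can be generated (and discarded)
#'   one at a time without materializing the whole cohort.
#' @export
synthesize_cohort_recording <- function(condition = c("control", "hyper"),
                                        index, seed = 1L,
                                        grid = electrode_grid(12, 12),
                                        duration = 30,
                                        sampling_rate = 3000) {
  condition <- match.arg(condition)
  preset <- cohort_preset(condition)
  cond_off <- if (condition == "hyper") 500000L else 0L
  center <- c((grid$n_rows - 1) / 2, (grid$n_cols - 1) / 2)
  seed_i <- as.integer(seed) + cond_off + as.integer(index) * 1000L
  cfg <- spike_gen_config(base_rate = preset$base_rate,
                          burst_on_rate = preset$burst_on_rate,
                          seed = seed_i)
  tr <- synthesize_spike_trains(cfg, duration, grid)
  n_ev <- withr::with_seed(seed_i + 7L,
                           stats::rpois(1, preset$lfp_event_rate * duration))
  onsets <- withr::with_seed(seed_i + 8L,
                             sort(stats::runif(max(n_ev, 1), 0.5,
                                               duration - 0.5)))
  wave <- lfp_wave_config(center, peak_amplitude = preset$lfp_peak_uv,
                          onset_times = onsets)
  out <- synthesize_recording(tr$spikes, list(wave), cfg, grid,
                              sampling_rate = sampling_rate)
  out$ground_truth$condition <- condition
  out$recording$meta <- list(condition = condition, index = index)
  out
}

#' Deterministic analytic test fields
#'
#' Closed-form voltage fields whose Laplacian (hence CSD) is known exactly:
#' `"uniform"` (constant `c`), `"delta"` (1 at one electrode, 0 elsewhere),
#' `"sinusoid"` (`sin(kx * x) * sin(ky * y)` with x = col, y = row in pitch
#' units), and `"dipole"` (a Gaussian source patch plus a Gaussian sink
#' patch of exactly equal integral, oscillating at `f_hz`).
#'
#' @param kind One of `"uniform"`, `"delta"`, `"sinusoid"`, `"dipole"`.
#' @param params Named list of kind-specific parameters: `value`
#'   (uniform); `at = c(row, col)` (delta); `kx`, `ky` in rad/pitch
#'   (sinusoid; must be < pi, the spatial Nyquist limit); `center_source`,
#'   `center_sink`, `sigma`, `amplitude`, `f_hz` (dipole).
#' @param grid An [electrode_grid()].
#' @param n_samples Number of time samples (default 1 for static kinds).
#' @param sampling_rate Hz.
#' @return An [mea_recording()] (marked filtered: these are LFP-band
#'   fields by construction).
#' @export
make_analytic_field <- function(kind = c("uniform", "delta", "sinusoid",
                                         "dipole"),
                                params = list(), grid = electrode_grid(16, 16),
                                n_samples = 1L, sampling_rate = 9000) {
  kind <- match.arg(kind)
  stopifnot_grid(grid)
  nr <- grid$n_rows; nc <- grid$n_cols
  frame <- switch(kind,
    uniform = matrix(params$value %||% 1, nr, nc),
    delta = {
      at <- params$at %||% c(nr %/% 2, nc %/% 2)
      m <- matrix(0, nr, nc); m[at[1] + 1L, at[2] + 1L] <- 1; m
    },
    sinusoid = {
      kx <- params$kx %||% 0.2; ky <- params$ky %||% 0.2
      if (kx >= pi || ky >= pi) {
        stop("spatial frequency at or above the Nyquist limit pi rad/pitch",
             call. = FALSE)
      }
      outer(0:(nr - 1L), 0:(nc - 1L), function(y, x) sin(kx * x) * sin(ky * y))
    },
    dipole = {
      sigma <- params$sigma %||% 1.5
      cs <- params$center_source %||% c(nr / 2, nc / 4)
      ck <- params$center_sink %||% c(nr / 2, 3 * nc / 4)
      g <- function(ctr) {
        m <- outer(0:(nr - 1L), 0:(nc - 1L), function(y, x)
          exp(-((y - ctr[1])^2 + (x - ctr[2])^2) / (2 * sigma^2)))
        m / sum(m)   # unit integral, so source - sink sums to exactly 0
      }
      (params$amplitude %||% 100) * (g(cs) - g(ck))
    })
  tcourse <- if (kind == "dipole") {
    f <- params$f_hz %||% 5
    sin(2 * pi * f * (0:(n_samples - 1L)) / sampling_rate)
  } else {
    rep(1, n_samples)
  }
  sig <- array(as.vector(frame) %o% tcourse, dim = c(nr, nc, n_samples))
  mea_recording(sig, sampling_rate = sampling_rate, grid = grid,
                meta = list(field_kind = kind), filtered = TRUE)
}
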