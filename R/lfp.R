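#' LFP detection parameters
#'
#' Defaults are the standard settings of the pipeline: order-5 IIR low-pass
#' at 200 Hz; hard double threshold at +40 / -40 uV; event duration from a
#' 50 ms energy window walked forward and backward from the peak until the
#' window energy drops to 1.5x the noise energy; 50 ms refractory period
#' per electrode; an electrode counts as active at >= 0.05 events/s; an
#' event is valid only if at least 40% of its area's electrodes host a
#' coincident event within a 300 ms window.
#'
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @param filter_order IIR filter order.
#' @param upper_uv,lower_uv Detection thresholds, uV (lower is negative).
#' @param energy_window_ms Sliding energy window, ms.
#' @param energy_factor Energy-above-noise factor ending the duration walk.
#' @param refractory_ms Minimum distance between two events on one
#'   electrode, ms.
#' @param active_rate_min Minimum event rate (events/s) for an electrode to
#'   count as active.
#' @param coincidence_fraction Minimum fraction of an area's total
#'   electrodes hosting a coincident event (inclusive comparison).
#' @param coincidence_window_ms Coincidence window, ms.
#' @param refractory_keep Which of two events closer than the refractory
#'   period survives: `"first"` (default) or `"largest"`.
#' @return A list of class `lfp_params`.
#' @export
lfp_params <- function(cutoff_hz = 200, filter_order = 5,
                       upper_uv = 40, lower_uv = -40,
                       energy_window_ms = 50, energy_factor = 1.5,
                       refractory_ms = 50, active_rate_min = 0.05,
                       coincidence_fraction = 0.40,
                       coincidence_window_ms = 300,
                       refractory_keep = c("first", "largest")) {
  stopifnot(cutoff_hz > 0, filter_order >= 1, upper_uv > 0, lower_uv < 0,
            energy_window_ms > 0, energy_factor > 0, refractory_ms > 0,
            active_rate_min >= 0, coincidence_fraction > 0,
            coincidence_fraction <= 1, coincidence_window_ms > 0)
  refractory_keep <- match.arg(refractory_keep)
  structure(as.list(environment()), class = "lfp_params")
}

#' Low-pass filter a recording for LFP analysis
#'
#' Causal single-pass Butterworth (maximally flat) IIR low-pass, applied
#' per electrode.  Single-pass keeps the effective order equal to
#' `order` (a zero-phase double pass would double it) at the price of a
#' frequency-dependent group delay.  DC gain is unity, the -3 dB point sits
#' at `cutoff_hz`.
#'
#' @param rec An [mea_recording()].
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist.
#' @param order Filter order (default 5).
#' @return The filtered [mea_recording()], `filtered` flag set.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 200, order = 5) {
  stopifnot(inherits(rec, "mea_recording"))
  if (cutoff_hz >= rec$sampling_rate / 2) {
    stop("cutoff must be below the Nyquist frequency ",
         rec$sampling_rate / 2, " Hz", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (rec$sampling_rate / 2),
                       type = "low")
  d <- dim(rec$signal)
  m <- matrix(rec$signal, nrow = d[1] * d[2], ncol = d[3])
  for (i in seq_len(nrow(m))) {
    m[i, ] <- signal::filter(bf, m[i, ])
  }
  out <- rec
  out$signal <- array(m, dim = d)
  out$filtered <- TRUE
  out
}

#' Noise energy of a trace from median windowed energy
#'
#' The energy (mean of squared samples) is computed on every sliding
#' window of `window_ms`; the noise energy is the median over all windows.
#' The median is robust as long as genuine events occupy less than half of
#' the windows, so no separate noise epoch needs to be identified.
#'
#' @param x Numeric trace (low-pass filtered), uV.
#' @param sampling_rate Hz.
#' @param window_ms Window length, ms (default 50).
#' @return Scalar noise energy in uV^2.
#' @export
estimate_noise_energy <- function(x, sampling_rate, window_ms = 50) {
  win <- max(1L, round(window_ms / 1000 * sampling_rate))
  if (length(x) < 10L * win) {
    stop("trace must be at least 10 windows long", call. = FALSE)
  }
  stats::median(window_energies(x, win))
}

# mean squared value of every length-`win` sliding window (step 1 sample)
window_energies <- function(x, win) {
  cs <- cumsum(c(0, x^2))
  (cs[(win + 1L):length(cs)] - cs[1:(length(cs) - win)]) / win
}

#' Detect LFP events by hard double-threshold crossing
#'
#' Per electrode of a low-pass-filtered recording: every maximal excursion
#' beyond the upper or lower threshold seeds an event whose peak is the
#' extremum of the excursion and whose amplitude is the signed voltage at
#' the peak.  Events closer than the refractory period are merged
#' (first-kept by default).  Each surviving event receives an energy-walk
#' duration ([estimate_event_duration()]) and an energy
#' `sum(|V|) * dt` in uV*ms over the duration span.  Electrodes with an
#' event rate of at least `p$active_rate_min` are flagged active.
#'
#' @param rec A low-pass filtered [mea_recording()] (a warning, not a
#'   failure, is issued if the filtered flag is missing).
#' @param p An [lfp_params()] object.
#' @return A tibble of class `lfp_events` with columns `row`, `col`,
#'   `peak_time_s`, `amplitude_uv`, `duration_ms`, `energy_uv_ms`,
#'   `edge_truncated`, `valid` (NA until [clean_events_by_area()] runs),
#'   `area` (NA likewise).  Attribute `electrodes` holds the
#'   per-electrode `(row, col, n_events, rate_per_s, active)` summary.
#' @export
detect_lfp_events <- function(rec, p = lfp_params()) {
  stopifnot(inherits(rec, "mea_recording"), inherits(p, "lfp_params"))
  if (!rec$filtered) {
    warning("recording is not flagged as low-pass filtered; ",
            "detecting on the raw band", call. = FALSE)
  }
  fs <- rec$sampling_rate
  duration <- rec_duration(rec)
  el <- grid_electrodes(rec$grid)
  rows <- purrr::map_dfr(seq_len(nrow(el)), function(i) {
    x <- electrode_trace(rec, el$row[i], el$col[i])
    ev <- detect_events_trace(x, fs, p)
    if (!nrow(ev)) return(NULL)
    dplyr::mutate(ev, row = el$row[i], col = el$col[i], .before = 1)
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(row = integer(), col = integer(),
                           peak_time_s = numeric(), amplitude_uv = numeric(),
                           duration_ms = numeric(), energy_uv_ms = numeric(),
                           edge_truncated = logical())
  }
  rows$valid <- NA
  rows$area <- NA_character_
  electrodes <- rows |>
    dplyr::group_by(row, col) |>
    dplyr::summarise(n_events = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(rate_per_s = n_events / duration,
                  active = rate_per_s >= p$active_rate_min)
  structure(rows, class = c("lfp_events", class(tibble::tibble())),
            duration_s = duration, grid = rec$grid, params = p,
            electrodes = electrodes)
}

# single-trace detection: excursions -> refractory merge -> duration/energy
detect_events_trace <- function(x, fs, p) {
  none <- tibble::tibble(peak_time_s = numeric(), amplitude_uv = numeric(),
                         duration_ms = numeric(), energy_uv_ms = numeric(),
                         edge_truncated = logical())
  over <- x > p$upper_uv | x < p$lower_uv
  if (!any(over)) return(none)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  peak_idx <- vapply(seq_along(starts), function(k) {
    span <- starts[k]:ends[k]
    span[which.max(abs(x[span]))]
  }, integer(1))
  peak_idx <- merge_refractory(peak_idx, abs(x[peak_idx]),
                               p$refractory_ms / 1000 * fs, p$refractory_keep)
  win <- max(1L, round(p$energy_window_ms / 1000 * fs))
  noise_e <- if (length(x) >= 10L * win) {
    stats::median(window_energies(x, win))
  } else {
    0   # trace too short for a noise estimate; the walk stops at the edges
  }
  dur <- purrr::map(peak_idx, function(pk)
    estimate_event_duration(x, pk, fs, window_ms = p$energy_window_ms,
                            energy_factor = p$energy_factor,
                            noise_energy = noise_e))
  dt_ms <- 1000 / fs
  tibble::tibble(
    peak_time_s = (peak_idx - 1) / fs,
    amplitude_uv = x[peak_idx],
    duration_ms = vapply(dur, `[[`, numeric(1), "duration_ms"),
    energy_uv_ms = vapply(dur, function(d)
      sum(abs(x[d$start_idx:d$end_idx])) * dt_ms, numeric(1)),
    edge_truncated = vapply(dur, `[[`, logical(1), "truncated"))
}

# refractory merge on sorted peak indices; keep first or largest per cluster
merge_refractory <- function(idx, mag, refr_n, keep = "first") {
  if (length(idx) < 2L) return(idx)
  out <- integer(0)
  cur <- idx[1L]; cur_mag <- mag[1L]
  for (k in 2:length(idx)) {
    if (idx[k] - cur < refr_n) {
      if (keep == "largest" && mag[k] > cur_mag) {
        cur <- idx[k]; cur_mag <- mag[k]
      }
      # "first": the earlier event is retained, the later discarded
    } else {
      out <- c(out, cur)
      cur <- idx[k]; cur_mag <- mag[k]
    }
  }
  c(out, cur)
}

#' Energy-walk event duration
#'
#' A window of `window_ms` slides sample-by-sample forward and backward
#' from the event peak for as long as its energy (mean squared value)
#' stays above `energy_factor` times the noise energy; the duration is the
#' span between the two stopping points.  If the energy is already at or
#' below the threshold at the peak, the minimal duration of one window is
#' returned; a walk that reaches the trace edge is truncated and flagged.
#'
#' @param x Numeric filtered trace, uV.
#' @param peak_idx Sample index of the event peak (1-based).
#' @param fs Sampling rate, Hz.
#' @param window_ms Window length, ms.
#' @param energy_factor Stop factor relative to noise energy.
#' @param noise_energy Noise energy in uV^2 (see [estimate_noise_energy()]).
#' @return List with `duration_ms`, `start_idx`, `end_idx`, `truncated`,
#'   `degenerate`.
#' @export
estimate_event_duration <- function(x, peak_idx, fs, window_ms = 50,
                                    energy_factor = 1.5, noise_energy) {
  n <- length(x)
  win <- max(1L, round(window_ms / 1000 * fs))
  thr <- energy_factor * noise_energy
  e_start <- window_energies(x, win)     # energy of window starting at s
  n_pos <- length(e_start)
  truncated <- FALSE

  # forward: first window start >= peak whose energy drops to <= thr
  fwd_range <- min(peak_idx, n_pos):n_pos
  fwd_hit <- fwd_range[e_start[fwd_range] <= thr][1]
  if (is.na(fwd_hit)) { fwd_hit <- n; truncated <- TRUE }
  # backward: last window END <= peak whose energy drops to <= thr
  end_pos <- win:n                        # window ending at e starts at e-win+1
  bwd_range <- max(peak_idx, win):win
  bwd_hit <- bwd_range[e_start[bwd_range - win + 1L] <= thr][1]
  if (is.na(bwd_hit)) { bwd_hit <- 1L; truncated <- TRUE }

  degenerate <- fwd_hit <= peak_idx && bwd_hit >= peak_idx
  span_ms <- (fwd_hit - bwd_hit) / fs * 1000
  duration_ms <- max(span_ms, window_ms)
  list(duration_ms = duration_ms,
       start_idx = min(bwd_hit, peak_idx), end_idx = max(fwd_hit, peak_idx),
       truncated = truncated,
       degenerate = degenerate || span_ms < window_ms)
}

#' Validate events by area-wide coincidence
#'
#' Genuine LFP events engage most of an anatomical area; isolated
#' single-electrode crossings are treated as spurious.  Each event is
#' assigned its electrode's area (events on electrodes outside every area
#' are dropped, with a message stating how many).  An event is valid iff,
#' within half the coincidence window on either side of its peak, at least
#' `coincidence_fraction` of the area's *total* electrodes (not only the
#' active ones) host an event.
#'
#' @param events An `lfp_events` tibble from [detect_lfp_events()].
#' @param areas An [area_masks()] table.
#' @param p An [lfp_params()] (fraction and window).
#' @return `events` with `area` filled in and `valid` TRUE/FALSE; invalid
#'   events are retained, out-of-area events removed.
#' @export
clean_events_by_area <- function(events, areas, p = attr(events, "params")) {
  stopifnot(inherits(events, "lfp_events"), inherits(areas, "area_masks"))
  if (is.null(p)) p <- lfp_params()
  at <- tibble::as_tibble(areas)
  area_sizes <- dplyr::count(at, area, name = "n_total")
  ev <- tibble::as_tibble(events)
  ev$area <- NULL
  ev <- dplyr::left_join(ev, at, by = c("row", "col"))
  n_out <- sum(is.na(ev$area))
  if (n_out > 0) {
    message(n_out, " event(s) on electrodes outside every area dropped")
    ev <- ev[!is.na(ev$area), ]
  }
  half_w <- p$coincidence_window_ms / 1000 / 2
  ev$valid <- FALSE
  for (a in unique(ev$area)) {
    sel <- which(ev$area == a)
    n_total <- area_sizes$n_total[area_sizes$area == a]
    t <- ev$peak_time_s[sel]
    eid <- paste(ev$row[sel], ev$col[sel])
    valid_a <- vapply(seq_along(sel), function(k) {
      inwin <- abs(t - t[k]) <= half_w
      length(unique(eid[inwin])) >= p$coincidence_fraction * n_total
    }, logical(1))
    ev$valid[sel] <- valid_a
  }
  out <- ev[, c("row", "col", "peak_time_s", "amplitude_uv", "duration_ms",
                "energy_uv_ms", "edge_truncated", "valid", "area")]
  structure(out, class = class(events),
            duration_s = attr(events, "duration_s"),
            grid = attr(events, "grid"), params = p,
            electrodes = attr(events, "electrodes"), cleaned = TRUE)
}

#' Per-electrode and per-area LFP feature table
#'
#' Averages amplitude, duration and energy per electrode over its valid
#' events, reports the event rate in events/min, and pools electrodes by
#' area.  Only valid events on active electrodes enter; with none, an
#' empty table is returned with `any_valid = FALSE`.
#'
#' @param events A cleaned `lfp_events` tibble (after
#'   [clean_events_by_area()]; uncleaned events with `valid = NA` are
#'   treated as valid so the table also works without area masks).
#' @param duration Recording duration, seconds.
#' @param active_rate_min Activity criterion, events/s (default from the
#'   event table's parameters).
#' @return A list of class `lfp_feature_table`: `electrodes` (per-electrode
#'   means), `areas` (per-area pooled means), `n_active_sites`,
#'   `any_valid`.
#' @export
lfp_feature_table <- function(events, duration = attr(events, "duration_s"),
                              active_rate_min = NULL) {
  stopifnot(inherits(events, "lfp_events"))
  p <- attr(events, "params")
  if (is.null(active_rate_min)) {
    active_rate_min <- if (!is.null(p)) p$active_rate_min else 0.05
  }
  ev <- tibble::as_tibble(events)
  ev <- ev[is.na(ev$valid) | ev$valid, ]
  elec <- attr(events, "electrodes")
  if (!is.null(elec)) {
    act <- elec[elec$active, c("row", "col")]
    ev <- dplyr::semi_join(ev, act, by = c("row", "col"))
  }
  if (!nrow(ev)) {
    return(structure(list(
      electrodes = tibble::tibble(), areas = tibble::tibble(),
      n_active_sites = 0L, any_valid = FALSE),
      class = "lfp_feature_table"))
  }
  per_el <- ev |>
    dplyr::group_by(row, col, area) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      rate_per_min = dplyr::n() / duration * 60,
      mean_amplitude_uv = mean(amplitude_uv),
      mean_abs_amplitude_uv = mean(abs(amplitude_uv)),
      mean_duration_ms = mean(duration_ms),
      mean_energy_uv_ms = mean(energy_uv_ms),
      .groups = "drop")
  per_area <- per_el |>
    dplyr::group_by(area) |>
    dplyr::summarise(
      n_electrodes = dplyr::n(),
      rate_per_min = mean(rate_per_min),
      mean_amplitude_uv = mean(mean_amplitude_uv),
      mean_abs_amplitude_uv = mean(mean_abs_amplitude_uv),
      mean_duration_ms = mean(mean_duration_ms),
      mean_energy_uv_ms = mean(mean_energy_uv_ms),
      .groups = "drop")
  structure(list(electrodes = per_el, areas = per_area,
                 n_active_sites = nrow(per_el), any_valid = TRUE),
            class = "lfp_feature_table")
}

#' @export
print.lfp_feature_table <- function(x, ...) {
  cat(sprintf("<lfp_feature_table> %d active site(s)%s\n", x$n_active_sites,
              if (!x$any_valid) " [no valid events]" else ""))
  if (x$any_valid && nrow(x$areas)) print(x$areas)
  invisible(x)
}
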