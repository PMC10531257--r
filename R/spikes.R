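#' Detect spikes by robust-SD thresholding
#'
#' Per electrode, the noise SD is estimated robustly as
#' `median(|signal|) / 0.6745` (the MAD-to-SD factor for Gaussian noise,
#' insensitive to the spikes themselves) and the detection threshold is
#' `sd_factor` times that estimate.  A spike is registered at every local
#' extremum that exceeds the threshold — negative-going minima for
#' `polarity = "negative"` (the usual extracellular convention), extrema of
#' either sign for `"both"` — and a dead time is enforced: after each
#' accepted spike, candidates within `dead_time_ms` are discarded.
#'
#' @param rec An [mea_recording()] in the spike band (do not low-pass
#'   filter first).
#' @param sd_factor Threshold in robust noise SDs (default 5).
#' @param polarity `"negative"` or `"both"`.
#' @param dead_time_ms Minimum separation between spikes on one electrode,
#'   milliseconds (> 0, default 1).
#' @return A [spike_trains()] tibble `(row, col, time_s)`.
#' @export
detect_spikes <- function(rec, sd_factor = 5,
                          polarity = c("negative", "both"),
                          dead_time_ms = 1) {
  stopifnot(inherits(rec, "mea_recording"))
  polarity <- match.arg(polarity)
  if (dead_time_ms <= 0) stop("`dead_time_ms` must be > 0", call. = FALSE)
  fs <- rec$sampling_rate
  dead_n <- dead_time_ms / 1000 * fs
  el <- grid_electrodes(rec$grid)
  out <- purrr::map_dfr(seq_len(nrow(el)), function(i) {
    x <- electrode_trace(rec, el$row[i], el$col[i])
    thr <- sd_factor * stats::median(abs(x)) / 0.6745
    if (thr <= 0) return(NULL)
    idx <- spike_candidates(x, thr, polarity)
    idx <- enforce_dead_time(idx, dead_n)
    if (!length(idx)) return(NULL)
    tibble::tibble(row = el$row[i], col = el$col[i], time_s = (idx - 1) / fs)
  })
  spike_trains(out, duration = rec_duration(rec), grid = rec$grid)
}

# indices of threshold-exceeding local extrema
spike_candidates <- function(x, thr, polarity) {
  n <- length(x)
  if (n < 3L) return(integer())
  mid <- 2:(n - 1L)
  minima <- x[mid] <= x[mid - 1L] & x[mid] <= x[mid + 1L] & x[mid] < -thr
  hits <- minima
  if (polarity == "both") {
    maxima <- x[mid] >= x[mid - 1L] & x[mid] >= x[mid + 1L] & x[mid] > thr
    hits <- hits | maxima
  }
  mid[hits]
}

# greedy first-kept dead-time pass over sorted candidate indices
enforce_dead_time <- function(idx, dead_n) {
  if (length(idx) < 2L) return(idx)
  keep <- idx[1L]
  last <- idx[1L]
  for (k in idx[-1L]) {
    if (k - last >= dead_n) {
      keep <- c(keep, k)
      last <- k
    }
  }
  keep
}

#' Per-electrode spike statistics (NOS, MFR, ISI)
#'
#' Computes the number of spikes (NOS), mean firing rate
#' (MFR = NOS / duration, spikes/s) and mean interspike interval (ISI, ms)
#' for every electrode with at least one spike.  The ISI is undefined (NA)
#' for electrodes with fewer than two spikes and such electrodes are
#' excluded from pooled ISI summaries, which [glance()][generics::glance]
#' reports as medians and quartiles for box plots.
#'
#' @param spikes A [spike_trains()] table.
#' @param duration Recording duration in seconds; defaults to the table's
#'   own `duration_s` attribute.
#' @return A tibble of class `spike_stats` with columns `row`, `col`,
#'   `nos`, `mfr`, `mean_isi_ms`.
#' @export
spike_statistics <- function(spikes, duration = train_duration(spikes)) {
  stopifnot(is.numeric(duration), duration > 0)
  st <- tibble::as_tibble(spikes) |>
    dplyr::group_by(row, col) |>
    dplyr::summarise(
      nos = dplyr::n(),
      mean_isi_ms = if (dplyr::n() >= 2) mean(diff(time_s)) * 1000
                    else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(mfr = nos / duration) |>
    dplyr::select(row, col, nos, mfr, mean_isi_ms)
  structure(st, class = c("spike_stats", class(tibble::tibble())),
            duration_s = duration, grid = train_grid(spikes))
}

#' @export
glance.spike_stats <- function(x, ...) {
  q <- function(v) stats::quantile(v, c(.25, .5, .75), na.rm = TRUE,
                                   names = FALSE)
  qm <- q(x$mfr); qn <- q(x$nos); qi <- q(x$mean_isi_ms)
  tibble::tibble(
    n_electrodes = nrow(x),
    total_nos = sum(x$nos),
    mfr_q1 = qm[1], mfr_median = qm[2], mfr_q3 = qm[3],
    nos_q1 = qn[1], nos_median = qn[2], nos_q3 = qn[3],
    isi_q1_ms = qi[1], isi_median_ms = qi[2], isi_q3_ms = qi[3])
}

#' Detect bursts with the max-ISI method
#'
#' A burst is a maximal run of consecutive spikes on one electrode in which
#' every interspike gap is at most `max_isi_ms`, containing at least
#' `min_spikes` spikes.  Burst duration is last minus first spike time.
#'
#' @param spikes A [spike_trains()] table.
#' @param max_isi_ms Largest within-burst interspike interval, ms (> 0;
#'   default 100).
#' @param min_spikes Minimum spikes per burst (>= 2; default 5).
#' @return A tibble of class `burst_set` with columns `row`, `col`,
#'   `start_s`, `end_s`, `n_spikes`.
#' @export
detect_bursts <- function(spikes, max_isi_ms = 100, min_spikes = 5) {
  stopifnot(max_isi_ms > 0, min_spikes >= 2)
  out <- tibble::as_tibble(spikes) |>
    dplyr::group_by(row, col) |>
    dplyr::reframe(burst_runs(time_s, max_isi_ms / 1000, min_spikes))
  structure(out, class = c("burst_set", class(tibble::tibble())),
            duration_s = train_duration(spikes), grid = train_grid(spikes),
            min_spikes = min_spikes)
}

# maximal qualifying runs in one sorted train
burst_runs <- function(t, max_isi_s, min_spikes) {
  if (length(t) < min_spikes) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          n_spikes = integer()))
  }
  # run boundaries where the gap exceeds max_isi
  brk <- c(0L, which(diff(t) > max_isi_s), length(t))
  starts <- brk[-length(brk)] + 1L
  ends <- brk[-1L]
  len <- ends - starts + 1L
  ok <- len >= min_spikes
  tibble::tibble(start_s = t[starts[ok]], end_s = t[ends[ok]],
                 n_spikes = len[ok])
}

#' Pooled burst statistics
#'
#' Mean burst duration (ms), mean spikes per burst, and burst frequency in
#' bursts per minute, over electrodes that burst at all.  With no bursts an
#' empty, flagged summary is returned (not zeros).
#'
#' @param bursts A `burst_set` from [detect_bursts()].
#' @param duration Recording duration, seconds.
#' @return A one-row tibble `(n_bursts, n_bursting_electrodes,
#'   mean_duration_ms, mean_spikes_per_burst, burst_rate_per_min,
#'   any_bursts)`; `any_bursts = FALSE` flags the empty case and the means
#'   are NA.
#' @export
burst_statistics <- function(bursts, duration = attr(bursts, "duration_s")) {
  b <- tibble::as_tibble(bursts)
  if (!nrow(b)) {
    return(tibble::tibble(n_bursts = 0L, n_bursting_electrodes = 0L,
                          mean_duration_ms = NA_real_,
                          mean_spikes_per_burst = NA_real_,
                          burst_rate_per_min = NA_real_, any_bursts = FALSE))
  }
  per_el <- b |>
    dplyr::group_by(row, col) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  tibble::tibble(
    n_bursts = nrow(b),
    n_bursting_electrodes = nrow(per_el),
    mean_duration_ms = mean((b$end_s - b$start_s) * 1000),
    mean_spikes_per_burst = mean(b$n_spikes),
    burst_rate_per_min = mean(per_el$n / duration * 60),
    any_bursts = TRUE)
}

#' Detect network bursts
#'
#' Time is binned at `bin_ms`; a bin is marked when the fraction of active
#' electrodes that are inside a burst during that bin reaches
#' `participation_fraction`.  Contiguous marked bins merge into network
#' bursts.  The denominator defaults to the number of electrodes carrying
#' at least one burst; pass `n_active` to use another active-electrode
#' count (e.g. the >= 0.1 spikes/s criterion of [active_electrodes()]).
#'
#' @param bursts A `burst_set` from [detect_bursts()].
#' @param bin_ms Bin width, ms (default 10).
#' @param participation_fraction Fraction of active electrodes that must be
#'   bursting simultaneously, in (0, 1] (default 0.2).
#' @param n_active Denominator for the participation fraction.
#' @param duration Recording duration, seconds.
#' @return A tibble of class `network_burst_set` with columns `start_s`,
#'   `end_s`, `duration_ms`, `max_participation`.
#' @export
detect_network_bursts <- function(bursts, bin_ms = 10,
                                  participation_fraction = 0.2,
                                  n_active = NULL,
                                  duration = attr(bursts, "duration_s")) {
  stopifnot(participation_fraction > 0, participation_fraction <= 1,
            bin_ms > 0)
  b <- tibble::as_tibble(bursts)
  empty <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                          duration_ms = numeric(),
                          max_participation = numeric())
  class(empty) <- c("network_burst_set", class(empty))
  if (!nrow(b)) return(empty)
  if (is.null(n_active)) {
    n_active <- nrow(dplyr::distinct(b, row, col))
  }
  bin_s <- bin_ms / 1000
  n_bins <- ceiling(duration / bin_s)
  # per bin, number of distinct electrodes inside a burst
  counts <- integer(n_bins)
  per_el <- split(b, paste(b$row, b$col))
  for (eb in per_el) {
    marked <- logical(n_bins)
    i0 <- pmax(floor(eb$start_s / bin_s) + 1L, 1L)
    i1 <- pmin(floor(eb$end_s / bin_s) + 1L, n_bins)
    for (k in seq_len(nrow(eb))) marked[i0[k]:i1[k]] <- TRUE
    counts <- counts + marked
  }
  hit <- counts / n_active >= participation_fraction
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values
  out <- tibble::tibble(
    start_s = (starts[ok] - 1L) * bin_s,
    end_s = pmin(ends[ok] * bin_s, duration),
    max_participation = vapply(seq_along(starts)[ok], function(i)
      max(counts[starts[i]:ends[i]]) / n_active, numeric(1)))
  out$duration_ms <- (out$end_s - out$start_s) * 1000
  out <- out[, c("start_s", "end_s", "duration_ms", "max_participation")]
  class(out) <- c("network_burst_set", class(tibble::tibble()))
  out
}

#' Active electrodes by firing rate
#'
#' @param stats A `spike_stats` table.
#' @param rate_min Minimum MFR in spikes/s (default 0.1).
#' @return The subset of `stats` rows with `mfr >= rate_min`.
#' @export
active_electrodes <- function(stats, rate_min = 0.1) {
  dplyr::filter(tibble::as_tibble(stats), mfr >= rate_min)
}

#' MFR activity map
#'
#' Lays the per-electrode mean firing rate out on the grid (zero where an
#' electrode never fired), for export or plotting.  The map conserves
#' activity: `sum(map) * duration` equals the total NOS.
#'
#' @param stats A `spike_stats` table from [spike_statistics()].
#' @param grid An [electrode_grid()]; defaults to the stats' grid.
#' @return A numeric `n_rows x n_cols` matrix of class `activity_map`
#'   (spikes/s).
#' @export
activity_map <- function(stats, grid = attr(stats, "grid")) {
  stopifnot_grid(grid)
  m <- matrix(0, grid$n_rows, grid$n_cols)
  s <- tibble::as_tibble(stats)
  m[cbind(s$row + 1L, s$col + 1L)] <- s$mfr
  structure(m, class = c("activity_map", "matrix", "array"),
            duration_s = attr(stats, "duration_s"))
}
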