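#' Default pipeline configuration
#'
#' The full configuration tree with every stage parameter at its default
#' (detection and cleaning parameters at the standard values documented in
#' [lfp_params()]).  User configs may override any subset; unknown keys
#' are rejected, so typos fail loudly.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "hdmea_run",
    input = NULL,
    stages = list(synth = FALSE, spikes = FALSE, network = FALSE,
                  lfp = FALSE, csd = FALSE),
    synth = list(condition = "control", n_rows = 12L, n_cols = 12L,
                 duration_s = 30, sampling_rate_hz = 3000),
    spikes = list(sd_factor = 5, polarity = "negative", dead_time_ms = 1,
                  max_isi_ms = 100, min_spikes = 5, nb_bin_ms = 10,
                  nb_participation = 0.2, active_rate_min = 0.1),
    network = list(bin_ms = 5, max_lag_ms = 150, n_surrogates = 20,
                   alpha = 0.001, jitter_ms = 50, active_rate_min = 0.1),
    lfp = list(cutoff_hz = 200, filter_order = 5, upper_uv = 40,
               lower_uv = -40, energy_window_ms = 50, energy_factor = 1.5,
               refractory_ms = 50, active_rate_min = 0.05,
               coincidence_fraction = 0.4, coincidence_window_ms = 300,
               area_masks = NULL),
    csd = list(sigma_pitch = 1, sat_threshold_uv = 4000,
               max_saturated_fraction = 0.5)
  )
}

# merge `user` into `base`, rejecting keys absent from `base`
merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!(nm %in% names(base))) {
      stop("unknown configuration key: ", path, nm, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the toggled stages — synthesis (or ingest of an HDF5
#' recording), spike analysis, connectivity, LFP analysis, CSD analysis —
#' writing every artifact plus a manifest echoing the complete
#' configuration into `outdir`.  One global seed fans out to per-stage
#' seeds by fixed offsets, so toggling one stage does not reshuffle
#' another's randomness; re-running the same config is deterministic.
#'
#' @param config A nested list, or a path to a YAML file, overriding
#'   [default_config()].  Unknown keys are rejected.
#' @return The output directory path, invisibly.  Artifacts: always
#'   `manifest.json`; per stage, CSV tables (spike stats, bursts, edges,
#'   events, features), a GraphML export of the connectivity graph and
#'   JSON stage summaries.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  counts <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  rec <- NULL
  truth <- NULL
  if (isTRUE(cfg$stages$synth)) {
    run_stage("synth", {
      s <- cfg$synth
      out <- synthesize_cohort(s$condition, 1, seed = seed + 101L,
                               grid = electrode_grid(s$n_rows, s$n_cols),
                               duration = s$duration_s,
                               sampling_rate = s$sampling_rate_hz)[[1]]
      rec <- out$recording
      truth <- out$ground_truth
      write_recording(rec, file.path(outdir, "recording.h5"),
                      ground_truth = truth)
      counts$synth <- list(n_samples = n_samples(rec),
                            n_planted_spikes = nrow(truth$spikes %||%
                                                      tibble::tibble()))
      message(sprintf("[synth] condition=%s %dx%d %gs @ %g Hz",
                      s$condition, s$n_rows, s$n_cols, s$duration_s,
                      s$sampling_rate_hz))
    })
  } else if (!is.null(cfg$input)) {
    run_stage("ingest", {
      rec <- read_recording(cfg$input)
      message(sprintf("[ingest] %s", cfg$input))
    })
  }

  spikes <- NULL
  if (isTRUE(cfg$stages$spikes)) {
    run_stage("spikes", {
      if (is.null(rec)) stop("no recording: enable synth or give input")
      p <- cfg$spikes
      spikes <- detect_spikes(rec, sd_factor = p$sd_factor,
                               polarity = p$polarity,
                               dead_time_ms = p$dead_time_ms)
      st <- spike_statistics(spikes)
      bursts <- detect_bursts(spikes, max_isi_ms = p$max_isi_ms,
                              min_spikes = p$min_spikes)
      nb <- detect_network_bursts(bursts, bin_ms = p$nb_bin_ms,
                                  participation_fraction = p$nb_participation)
      utils::write.csv(tibble::as_tibble(st),
                       file.path(outdir, "spike_stats.csv"),
                       row.names = FALSE)
      utils::write.csv(tibble::as_tibble(bursts),
                       file.path(outdir, "bursts.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(pooled = glance(st), bursts = burst_statistics(bursts),
             network_bursts = tibble::as_tibble(nb)),
        file.path(outdir, "spike_summary.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
      counts$spikes <- list(n_spikes = nrow(spikes), n_bursts = nrow(bursts),
                             n_network_bursts = nrow(nb))
      message(sprintf("[spikes] %d spikes, %d bursts, %d network bursts",
                      nrow(spikes), nrow(bursts), nrow(nb)))
    })
  }

  if (isTRUE(cfg$stages$network)) {
    run_stage("network", {
      if (is.null(spikes)) stop("network stage needs the spikes stage")
      p <- cfg$network
      g <- infer_connectivity(spikes, bin_ms = p$bin_ms,
                              max_lag_ms = p$max_lag_ms,
                              n_surrogates = p$n_surrogates,
                              alpha = p$alpha, jitter_ms = p$jitter_ms,
                              active_rate_min = p$active_rate_min,
                              seed = seed + 303L)
      gm <- graph_metrics(g)
      roles <- classify_node_roles(g)
      utils::write.csv(tidy(g), file.path(outdir, "edges.csv"),
                       row.names = FALSE)
      igraph::write_graph(g$graph, file.path(outdir, "connectivity.graphml"),
                          format = "graphml")
      utils::write.csv(tibble::as_tibble(gm),
                       file.path(outdir, "graph_metrics.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(pooled = glance(gm),
             roles = dplyr::count(roles, role)),
        file.path(outdir, "network_summary.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
      counts$network <- list(n_nodes = nrow(g$nodes),
                              n_edges = igraph::ecount(g$graph))
      message(sprintf("[network] %d nodes, %d edges", nrow(g$nodes),
                      igraph::ecount(g$graph)))
    })
  }

  filtered <- NULL
  if (isTRUE(cfg$stages$lfp)) {
    run_stage("lfp", {
      if (is.null(rec)) stop("no recording: enable synth or give input")
      p <- cfg$lfp
      lp <- lfp_params(cutoff_hz = p$cutoff_hz, filter_order = p$filter_order,
                       upper_uv = p$upper_uv, lower_uv = p$lower_uv,
                       energy_window_ms = p$energy_window_ms,
                       energy_factor = p$energy_factor,
                       refractory_ms = p$refractory_ms,
                       active_rate_min = p$active_rate_min,
                       coincidence_fraction = p$coincidence_fraction,
                       coincidence_window_ms = p$coincidence_window_ms)
      filtered <- lowpass_filter(rec, p$cutoff_hz, p$filter_order)
      ev <- detect_lfp_events(filtered, lp)
      n_raw <- nrow(ev)
      if (!is.null(p$area_masks)) {
        areas <- read_area_masks(p$area_masks, rec$grid)
        ev <- clean_events_by_area(ev, areas, lp)
      }
      ft <- lfp_feature_table(ev)
      utils::write.csv(tibble::as_tibble(ev),
                       file.path(outdir, "lfp_events.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(electrodes = ft$electrodes, areas = ft$areas,
             n_active_sites = ft$n_active_sites),
        file.path(outdir, "lfp_features.json"),
        dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null")
      counts$lfp <- list(n_events = n_raw,
                          n_valid = sum(ev$valid %in% TRUE),
                          n_active_sites = ft$n_active_sites)
      message(sprintf("[lfp] %d events detected, %d valid, %d active sites",
                      n_raw, sum(ev$valid %in% TRUE), ft$n_active_sites))
    })
  }

  if (isTRUE(cfg$stages$csd)) {
    run_stage("csd", {
      if (is.null(rec)) stop("no recording: enable synth or give input")
      p <- cfg$csd
      base <- filtered %||% lowpass_filter(rec, cfg$lfp$cutoff_hz,
                                           cfg$lfp$filter_order)
      sat <- detect_saturation(base, p$sat_threshold_uv)
      base <- inpaint_saturated(base, sat, p$max_saturated_fraction)
      sm <- smooth_spatial(base, sigma = p$sigma_pitch)
      csd <- compute_csd(sm)
      amp <- hilbert_amplitude(base)
      mask <- select_roi(amp)
      rcsd <- NA_real_
      if (!mask$empty && !all(mask$roi)) {
        mask <- select_toi(amp, mask)
        rcsd <- rectified_csd(csd, mask)
      }
      jsonlite::write_json(
        list(rcsd = rcsd, roi_size = sum(mask$roi),
             saturated_fraction = attr(base, "saturated_fraction"),
             mu_noise = mask$mu_noise, sigma_noise = mask$sigma_noise),
        file.path(outdir, "csd_summary.json"), auto_unbox = TRUE,
        digits = NA, na = "null")
      counts$csd <- list(roi_size = sum(mask$roi), rcsd = rcsd)
      message(sprintf("[csd] ROI %d electrodes, rCSD %.4g", sum(mask$roi),
                      rcsd))
    })
  }

  jsonlite::write_json(
    list(package = "hdmea",
         version = as.character(utils::packageVersion("hdmea")),
         config = cfg, counts = counts),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null")
  invisible(outdir)
}

#' Welch's unpaired two-tailed t-test
#'
#' Group comparison helper used throughout the pipeline figures: an
#' unpaired, two-tailed t-test with Welch's correction (unequal
#' variances, Welch--Satterthwaite degrees of freedom), computed by
#' [stats::t.test()].
#'
#' @param a,b Numeric vectors, each with at least 2 values and nonzero
#'   variance.
#' @param labels Length-2 character vector of group labels.
#' @return An object of class `welch_htest` with `statistic` (t), `df`,
#'   `p_value`, group means and sizes; see [tidy()][generics::tidy] /
#'   [glance()][generics::glance].
#' @examples
#' welch_test(rnorm(10), rnorm(10, 2))
#' @export
welch_test <- function(a, b, labels = c("a", "b")) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2 ||
      stats::var(a) == 0 || stats::var(b) == 0) {
    stop("each group needs >= 2 values with nonzero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b),
                 labels = labels),
            class = "welch_htest")
}

#' @export
print.welch_htest <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: %s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g)\n",
              x$labels[1], x$n_a, x$mean_a, x$labels[2], x$n_b, x$mean_b))
  cat(sprintf("  t = %.4f, df = %.2f, p = %.4g\n", x$statistic, x$df,
              x$p_value))
  invisible(x)
}

#' @export
tidy.welch_htest <- function(x, ...) {
  tibble::tibble(estimate = x$mean_a - x$mean_b,
                 estimate1 = x$mean_a, estimate2 = x$mean_b,
                 statistic = x$statistic, p.value = x$p_value,
                 parameter = x$df, method = "Welch Two Sample t-test",
                 alternative = "two.sided")
}

#' @export
glance.welch_htest <- function(x, ...) tidy(x)

#' Summary metrics of one recording for group comparison
#'
#' Runs the three stages the condition contrast is read from and returns
#' one row: pooled mean firing rate (spikes/s over electrodes with any
#' spike), pooled LFP event rate (events/min over active electrodes, zero
#' with none), and the rectified CSD scalar (NA when the ROI is empty or
#' degenerate).
#'
#' @param rec An [mea_recording()].
#' @param spike_sd_factor Spike detection threshold factor.
#' @param p LFP detection parameters ([lfp_params()]).
#' @param sigma_pitch Spatial smoothing SD in pitch units.
#' @return A one-row tibble `(mfr, lfp_rate_per_min, rcsd)`.
#' @export
recording_summary <- function(rec, spike_sd_factor = 5, p = lfp_params(),
                              sigma_pitch = 1) {
  spikes <- detect_spikes(rec, sd_factor = spike_sd_factor)
  st <- spike_statistics(spikes, rec_duration(rec))
  mfr <- if (nrow(st)) mean(st$mfr) else 0
  lp <- lowpass_filter(rec, p$cutoff_hz, p$filter_order)
  ev <- detect_lfp_events(lp, p)
  el <- attr(ev, "electrodes")
  lfp_rate <- if (!is.null(el) && any(el$active)) {
    mean(el$rate_per_s[el$active]) * 60
  } else 0
  amp <- hilbert_amplitude(lp)
  mask <- select_roi(amp)
  rcsd <- NA_real_
  if (!mask$empty && !all(mask$roi)) {
    mask <- select_toi(amp, mask)
    csd <- compute_csd(smooth_spatial(lp, sigma_pitch))
    rcsd <- suppressWarnings(rectified_csd(csd, mask))
  }
  tibble::tibble(mfr = mfr, lfp_rate_per_min = lfp_rate, rcsd = rcsd)
}
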