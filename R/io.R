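#' Write a recording to the HDF5 container
#'
#' On-disk layout: group `/recording` holds the dataset `signal`
#' (`n_rows x n_cols x n_samples`, microvolts) and the attributes
#' `sampling_rate_hz`, `pitch_um`, `electrode_um` and `filtered`; free-form
#' metadata goes to `/meta` as scalar attributes; if the recording carries
#' planted ground truth (see [synthesize_recording()]) it is serialized
#' losslessly under `/ground_truth`.  Unknown extra groups are ignored on
#' read, so the container is forward-extensible.
#'
#' The signal is stored as float64 so that a write/read round trip is
#' bit-exact on every field; pass `storage = "float32"` for half-size files
#' when exactness beyond single precision is not needed.
#'
#' @param rec An [mea_recording()].
#' @param path Destination file path; an existing file is overwritten.
#' @param ground_truth Optional `ground_truth` object to embed.
#' @param storage `"float64"` (default, lossless) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, ground_truth = NULL,
                            storage = c("float64", "float32")) {
  stopifnot(inherits(rec, "mea_recording"))
  storage <- match.arg(storage)
  if (!all(is.finite(rec$signal))) {
    stop("invalid recording: signal contains non-finite values", call. = FALSE)
  }
  if (file.exists(path)) file.remove(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop("cannot create HDF5 file at ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  rhdf5::h5createGroup(path, "recording")
  d <- dim(rec$signal)
  rhdf5::h5createDataset(
    path, "recording/signal", dims = d,
    H5type = if (storage == "float32") "H5T_IEEE_F32LE" else "H5T_IEEE_F64LE",
    chunk = c(d[1], d[2], min(d[3], 4096L)), level = 0L)
  rhdf5::h5write(rec$signal, path, "recording/signal")
  if (length(rec$meta)) rhdf5::h5createGroup(path, "meta")
  rhdf5::h5closeAll()

  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "recording")
  rhdf5::h5writeAttribute(rec$sampling_rate, gid, "sampling_rate_hz")
  rhdf5::h5writeAttribute(rec$grid$pitch_um, gid, "pitch_um")
  rhdf5::h5writeAttribute(rec$grid$electrode_um, gid, "electrode_um")
  rhdf5::h5writeAttribute(as.integer(rec$filtered), gid, "filtered")
  rhdf5::H5Gclose(gid)

  if (length(rec$meta)) {
    mid <- rhdf5::H5Gopen(fid, "meta")
    for (nm in names(rec$meta)) {
      v <- rec$meta[[nm]]
      if (is.character(v) || is.numeric(v) || is.logical(v)) {
        rhdf5::h5writeAttribute(v, mid, nm)
      }
    }
    rhdf5::H5Gclose(mid)
  }
  rhdf5::H5Fclose(fid)

  if (!is.null(ground_truth)) write_ground_truth(ground_truth, path)
  invisible(path)
}

write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  rhdf5::h5createGroup(path, "ground_truth")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (!is.null(gt$spikes) && nrow(gt$spikes)) {
    rhdf5::h5write(as.integer(gt$spikes$row), path, "ground_truth/spike_row")
    rhdf5::h5write(as.integer(gt$spikes$col), path, "ground_truth/spike_col")
    rhdf5::h5write(gt$spikes$time_s, path, "ground_truth/spike_time_s")
  }
  if (!is.null(gt$lfp_events) && nrow(gt$lfp_events)) {
    rhdf5::h5write(as.data.frame(gt$lfp_events), path,
                   "ground_truth/lfp_events")
  }
  if (!is.null(gt$roi) && nrow(gt$roi)) {
    rhdf5::h5write(as.integer(gt$roi$row), path, "ground_truth/roi_row")
    rhdf5::h5write(as.integer(gt$roi$col), path, "ground_truth/roi_col")
  }
  rhdf5::h5closeAll()
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "ground_truth")
  rhdf5::h5writeAttribute(gt$condition %||% "unknown", gid, "condition")
  rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a recording from the HDF5 container
#'
#' @param path Path to a file written by [write_recording()] (layout
#'   documented there).
#' @return An [mea_recording()].  If the file carries a `/ground_truth`
#'   group it is attached as attribute `"ground_truth"`.  Unknown top-level
#'   groups are ignored with a warning.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- rhdf5::h5ls(path, recursive = FALSE)$name
  known <- c("recording", "meta", "ground_truth")
  extra <- setdiff(top, known)
  if (length(extra)) {
    warning("ignoring unknown group(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  if (!("recording" %in% top)) {
    stop("container format error: missing group '/recording'", call. = FALSE)
  }
  contents <- rhdf5::h5ls(path)
  if (!any(contents$group == "/recording" & contents$name == "signal")) {
    stop("container format error: missing dataset '/recording/signal'",
         call. = FALSE)
  }
  sig <- rhdf5::h5read(path, "recording/signal")
  att <- rhdf5::h5readAttributes(path, "recording")
  for (req in c("sampling_rate_hz", "pitch_um", "electrode_um")) {
    if (is.null(att[[req]])) {
      stop("container format error: missing attribute '", req,
           "' on /recording", call. = FALSE)
    }
  }
  meta <- list()
  if ("meta" %in% top) {
    meta <- lapply(rhdf5::h5readAttributes(path, "meta"), as.vector)
  }
  grid <- electrode_grid(dim(sig)[1], dim(sig)[2],
                         pitch_um = as.numeric(att$pitch_um),
                         electrode_um = as.numeric(att$electrode_um))
  rec <- mea_recording(sig, sampling_rate = as.numeric(att$sampling_rate_hz),
                       grid = grid, meta = meta,
                       filtered = isTRUE(as.integer(att$filtered %||% 0L) == 1L))
  if ("ground_truth" %in% top) {
    attr(rec, "ground_truth") <- read_ground_truth(path)
  }
  rec
}

read_ground_truth <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  gnames <- contents$name[contents$group == "/ground_truth"]
  spikes <- NULL
  if ("spike_time_s" %in% gnames) {
    spikes <- tibble::tibble(
      row = as.integer(rhdf5::h5read(path, "ground_truth/spike_row")),
      col = as.integer(rhdf5::h5read(path, "ground_truth/spike_col")),
      time_s = as.numeric(rhdf5::h5read(path, "ground_truth/spike_time_s")))
  }
  events <- NULL
  if ("lfp_events" %in% gnames) {
    events <- tibble::as_tibble(rhdf5::h5read(path, "ground_truth/lfp_events"))
  }
  roi <- NULL
  if ("roi_row" %in% gnames) {
    roi <- tibble::tibble(
      row = as.integer(rhdf5::h5read(path, "ground_truth/roi_row")),
      col = as.integer(rhdf5::h5read(path, "ground_truth/roi_col")))
  }
  att <- rhdf5::h5readAttributes(path, "ground_truth")
  ground_truth(spikes = spikes, lfp_events = events, roi = roi,
               condition = as.character(att$condition %||% "unknown"))
}

#' Ground-truth record for synthetic recordings
#'
#' Bundles the planted truth a synthetic recording was built from, so
#' downstream detectors can be scored against it.
#'
#' @param spikes Tibble `(row, col, time_s)` of planted spike times, or NULL.
#' @param lfp_events Tibble of planted LFP events
#'   `(row, col, onset_s, peak_time_s, amplitude_uv, duration_ms)`, or NULL.
#' @param roi Tibble `(row, col)` of the planted region of interest, or NULL.
#' @param condition Condition label (e.g. `"control"`, `"hyper"`).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(spikes = NULL, lfp_events = NULL, roi = NULL,
                         condition = "unknown") {
  structure(list(spikes = spikes, lfp_events = lfp_events, roi = roi,
                 condition = condition),
            class = "ground_truth")
}

#' Read anatomical area masks
#'
#' Areas (e.g. DG, CA1, CA3 of a hippocampal slice) are consumed as a JSON
#' file mapping area name to a list of `[row, col]` electrode pairs
#' (0-based).  Electrodes must lie inside the grid and may not be shared
#' between areas.
#'
#' @param path Path to the JSON mask file.
#' @param grid The [electrode_grid()] the masks apply to.
#' @return A tibble of class `area_masks` with columns `area`, `row`, `col`.
#' @export
read_area_masks <- function(path, grid) {
  stopifnot_grid(grid)
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!is.list(raw) || is.null(names(raw)) || !length(raw)) {
    stop("mask file must be a JSON object mapping area name -> [[row, col], ...]",
         call. = FALSE)
  }
  area_masks(
    purrr::imap_dfr(raw, function(m, nm) {
      m <- matrix(as.integer(m), ncol = 2)
      tibble::tibble(area = nm, row = m[, 1], col = m[, 2])
    }),
    grid = grid)
}

#' Construct/validate an area mask table
#'
#' @param x Tibble with columns `area`, `row`, `col` (0-based electrodes).
#' @param grid The [electrode_grid()] to validate against.
#' @return `x` with class `area_masks`.
#' @export
area_masks <- function(x, grid) {
  stopifnot_grid(grid)
  x <- tibble::as_tibble(x)[, c("area", "row", "col")]
  if (!nrow(x)) stop("area masks must be non-empty", call. = FALSE)
  bad <- !in_grid(x$row, x$col, grid)
  if (any(bad)) {
    stop(sprintf("electrode [%d, %d] of area '%s' is outside the %d x %d grid",
                 x$row[bad][1], x$col[bad][1], x$area[bad][1],
                 grid$n_rows, grid$n_cols), call. = FALSE)
  }
  key <- paste(x$row, x$col)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("electrode [", gsub(" ", ", ", d),
         "] belongs to more than one area", call. = FALSE)
  }
  class(x) <- c("area_masks", class(x))
  attr(x, "grid") <- grid
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
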