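#' Construct an HD-MEA recording
#'
#' The universal signal carrier of the pipeline: a microvolt-valued voltage
#' trace for every electrode of a rectangular grid.  The signal is stored as
#' a 3-dimensional array indexed `[row, col, sample]` (0-based electrode
#' coordinates map to array indices + 1).
#'
#' @param signal Numeric array of dimension `n_rows x n_cols x n_samples`,
#'   in microvolts.
#' @param sampling_rate Sampling rate in Hz (default 9000).
#' @param grid An [electrode_grid()]; its shape must match `signal`.
#' @param meta Named list of free-form metadata (subject id, condition
#'   label, DIV, ...).
#' @param filtered Logical flag: has the signal been low-pass filtered for
#'   LFP analysis?  Set by [lowpass_filter()].
#' @return An object of class `mea_recording`.
#' @seealso [write_recording()], [read_recording()], [synthesize_recording()]
#' @export
mea_recording <- function(signal, sampling_rate = 9000,
                          grid = electrode_grid(dim(signal)[1], dim(signal)[2]),
                          meta = list(), filtered = FALSE) {
  if (!is.array(signal) || length(dim(signal)) != 3L) {
    stop("`signal` must be a 3-d array [row, col, sample]", call. = FALSE)
  }
  stopifnot_grid(grid)
  if (dim(signal)[1] != grid$n_rows || dim(signal)[2] != grid$n_cols) {
    stop(sprintf("signal is %d x %d x %d but grid is %d x %d",
                 dim(signal)[1], dim(signal)[2], dim(signal)[3],
                 grid$n_rows, grid$n_cols), call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)",
         call. = FALSE)
  }
  structure(
    list(signal = signal, sampling_rate = as.numeric(sampling_rate),
         grid = grid, meta = meta, filtered = isTRUE(filtered)),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %s, %d samples @ %g Hz (%.3f s)%s\n",
    format(x$grid), n_samples(x), x$sampling_rate, rec_duration(x),
    if (x$filtered) ", low-pass filtered" else ""))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Recording duration and sample count
#'
#' @param rec An `mea_recording`.
#' @return `rec_duration()` the duration in seconds
#'   (`n_samples / sampling_rate`); `n_samples()` the number of samples.
#' @export
rec_duration <- function(rec) n_samples(rec) / rec$sampling_rate

#' @rdname rec_duration
#' @export
n_samples <- function(rec) dim(rec$signal)[3]

#' Flag saturated samples by amplitude thresholding
#'
#' Amplifier saturation clips the trace at the rail; such samples carry no
#' physiological information and must be inpainted before spatial analysis.
#' A sample is flagged saturated when `|signal| >= sat_threshold`
#' (inclusive comparison).  The occupied fraction is reported so the analyst
#' can judge whether inpainting is trustworthy.
#'
#' @param rec An [mea_recording()].
#' @param sat_threshold Saturation level in microvolts (> 0).  The default
#'   4000 uV is configurable; pick the rail of your amplifier.
#' @return An object of class `saturation_mask`: a list with `saturated`
#'   (logical array shaped like the signal) and `fraction` (proportion of
#'   saturated samples).
#' @seealso [inpaint_saturated()]
#' @export
detect_saturation <- function(rec, sat_threshold = 4000) {
  stopifnot(inherits(rec, "mea_recording"))
  if (!is.numeric(sat_threshold) || sat_threshold <= 0) {
    stop("`sat_threshold` must be > 0 (uV)", call. = FALSE)
  }
  sat <- abs(rec$signal) >= sat_threshold
  frac <- mean(sat)
  structure(list(saturated = sat, fraction = frac,
                 sat_threshold = sat_threshold),
            class = "saturation_mask")
}

#' @export
print.saturation_mask <- function(x, ...) {
  cat(sprintf("<saturation_mask> threshold %g uV, fraction %.4g\n",
              x$sat_threshold, x$fraction))
  invisible(x)
}

#' Long-format view of a recording
#'
#' @param x An `mea_recording`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `time_s`, `voltage_uv`.
#'   Intended for small recordings and plotting; the array form is the
#'   working representation.
#' @export
tidy.mea_recording <- function(x, ...) {
  d <- dim(x$signal)
  tibble::tibble(
    row = rep(rep(0:(d[1] - 1L), times = d[2]), times = d[3]),
    col = rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    time_s = rep((0:(d[3] - 1L)) / x$sampling_rate, each = d[1] * d[2]),
    voltage_uv = as.vector(x$signal)
  )
}

# single-electrode trace as a numeric vector (0-based coordinates)
electrode_trace <- function(rec, row, col) {
  rec$signal[row + 1L, col + 1L, ]
}
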