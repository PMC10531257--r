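#' Electrode grid geometry
#'
#' Describes the rectangular electrode array of an HD-MEA chip.  The default
#' geometry is the 64 x 64 CMOS grid with 42 um pitch and 21 x 21 um
#' electrodes (2.67 x 2.67 mm active area) sampled at 9 kHz elsewhere in the
#' pipeline.  Electrode positions are addressed 0-based as (row, col),
#' row-major; the spatial step of the CSD stencil is the pitch.
#'
#' @param n_rows,n_cols Number of electrode rows / columns (>= 2 each).
#' @param pitch_um Center-to-center electrode distance in micrometers.
#' @param electrode_um Electrode side length in micrometers; must be
#'   positive and strictly smaller than the pitch.
#' @return An object of class `electrode_grid`.
#' @examples
#' g <- electrode_grid()            # the 64 x 64 default
#' g2 <- electrode_grid(8, 8)
#' @export
electrode_grid <- function(n_rows = 64L, n_cols = 64L, pitch_um = 42,
                           electrode_um = 21) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 2L || n_cols < 2L) {
    stop("electrode grid must have n_rows >= 2 and n_cols >= 2", call. = FALSE)
  }
  if (!is.finite(pitch_um) || !is.finite(electrode_um) ||
      electrode_um <= 0 || pitch_um <= electrode_um) {
    stop("electrode grid requires pitch_um > electrode_um > 0", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         pitch_um = as.numeric(pitch_um),
         electrode_um = as.numeric(electrode_um)),
    class = "electrode_grid"
  )
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d, pitch %g um, electrode %g um\n",
              x$n_rows, x$n_cols, x$pitch_um, x$electrode_um))
  invisible(x)
}

#' @export
format.electrode_grid <- function(x, ...) {
  sprintf("%dx%d grid (pitch %g um)", x$n_rows, x$n_cols, x$pitch_um)
}

n_electrodes <- function(grid) grid$n_rows * grid$n_cols

# all electrode coordinates as a tibble, 0-based row/col
grid_electrodes <- function(grid) {
  tidyr::expand_grid(row = 0:(grid$n_rows - 1L), col = 0:(grid$n_cols - 1L))
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "electrode_grid")) {
    stop("`grid` must be an `electrode_grid` object", call. = FALSE)
  }
  invisible(grid)
}

in_grid <- function(row, col, grid) {
  row >= 0L & row < grid$n_rows & col >= 0L & col < grid$n_cols
}
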