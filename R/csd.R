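#' Inpaint saturated electrodes by harmonic interpolation
#'
#' At each time point, saturated samples are replaced by 2-D linear
#' interpolation from the surrounding non-saturated electrodes: the
#' saturated set is filled with the discrete harmonic extension of its
#' boundary values (iterated 4-neighbor averaging to convergence), which
#' reproduces planar gradients exactly and reduces to the neighbor mean
#' for isolated electrodes.  A frame whose saturated fraction exceeds
#' `max_saturated_fraction` has no trustworthy support and raises an
#' error.  The overall saturated fraction and the before/after energy
#' ratio of the inpainted samples are attached as attributes so artifacts
#' can be audited.
#'
#' @param rec An [mea_recording()].
#' @param mask A `saturation_mask` from [detect_saturation()], aligned
#'   with `rec`.
#' @param max_saturated_fraction Per-frame guard (default 0.5).
#' @return The inpainted [mea_recording()], with attributes
#'   `saturated_fraction` and `energy_ratio`.
#' @export
inpaint_saturated <- function(rec, mask, max_saturated_fraction = 0.5) {
  stopifnot(inherits(rec, "mea_recording"),
            inherits(mask, "saturation_mask"))
  if (!identical(dim(mask$saturated), dim(rec$signal))) {
    stop("saturation mask is not aligned with the recording", call. = FALSE)
  }
  if (mask$fraction == 0) {
    out <- rec
    attr(out, "saturated_fraction") <- 0
    attr(out, "energy_ratio") <- 1
    return(out)
  }
  sig <- rec$signal
  d <- dim(sig)
  frame_frac <- apply(mask$saturated, 3, mean)
  if (any(frame_frac > max_saturated_fraction)) {
    stop(sprintf("frame %d is %.0f%% saturated (> %.0f%% guard); inpainting refused",
                 which.max(frame_frac), 100 * max(frame_frac),
                 100 * max_saturated_fraction), call. = FALSE)
  }
  e_before <- 0; e_after <- 0
  for (t in which(frame_frac > 0)) {
    hole <- mask$saturated[, , t]
    frame <- sig[, , t]
    e_before <- e_before + sum(frame[hole]^2)
    frame <- harmonic_fill(frame, hole)
    e_after <- e_after + sum(frame[hole]^2)
    sig[, , t] <- frame
  }
  out <- rec
  out$signal <- sig
  attr(out, "saturated_fraction") <- mask$fraction
  attr(out, "energy_ratio") <- if (e_before > 0) e_after / e_before else NA_real_
  out
}

# discrete harmonic extension of `frame` into `hole` (logical matrix):
# Jacobi iteration of 4-neighbor means with valid values as Dirichlet data
harmonic_fill <- function(frame, hole, tol = 1e-10, max_iter = 2000L) {
  nr <- nrow(frame); nc <- ncol(frame)
  # seed holes with the mean of valid values for faster convergence
  frame[hole] <- mean(frame[!hole])
  pad <- function(m) {
    # replicate-pad so grid-edge electrodes average their existing neighbors
    rbind(m[1, , drop = FALSE], m, m[nr, , drop = FALSE])[
      , c(1, seq_len(nc), nc)]
  }
  scale0 <- max(abs(frame[!hole]), 1e-12)
  for (it in seq_len(max_iter)) {
    p <- pad(frame)
    nb <- (p[1:nr, 2:(nc + 1)] + p[3:(nr + 2), 2:(nc + 1)] +
             p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)]) / 4
    delta <- max(abs(nb[hole] - frame[hole]))
    frame[hole] <- nb[hole]
    if (delta < tol * scale0) break
  }
  frame
}

#' Spatial Gaussian smoothing
#'
#' Per-frame 2-D Gaussian convolution with standard deviation `sigma` in
#' units of the electrode pitch, truncated at 3 sigma and renormalized at
#' the grid boundary so that a constant field is a fixed point and frame
#' means are preserved on interior-dominated fields.  Implemented as a
#' separable row/column pass using normalized band matrices, so the whole
#' volume smooths in two matrix products.
#'
#' @param rec An [mea_recording()].
#' @param sigma Kernel SD in pitch units (> 0; default 1, i.e. sigma =
#'   d_pitch).
#' @return The smoothed [mea_recording()].
#' @export
smooth_spatial <- function(rec, sigma = 1) {
  stopifnot(inherits(rec, "mea_recording"), sigma > 0)
  d <- dim(rec$signal)
  s_row <- gaussian_smoother_matrix(d[1], sigma)
  s_col <- gaussian_smoother_matrix(d[2], sigma)
  # rows: S_r %*% X for every frame at once
  m <- matrix(rec$signal, nrow = d[1], ncol = d[2] * d[3])
  m <- s_row %*% m
  a <- array(m, dim = d)
  # columns: permute so the column index leads, multiply, permute back
  a <- aperm(a, c(2, 1, 3))
  m <- matrix(a, nrow = d[2], ncol = d[1] * d[3])
  m <- s_col %*% m
  a <- aperm(array(m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  out <- rec
  out$signal <- a
  out$meta$smoothed_sigma <- sigma
  out
}

# n x n one-dimensional normalized truncated-Gaussian smoothing matrix
gaussian_smoother_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    s[i, j[ok]] <- w[ok] / sum(w[ok])   # renormalize truncated tails
  }
  s
}

#' Two-dimensional current source density (9-point Laplacian)
#'
#' Estimates the CSD as the negated modified 2-D Laplacian of the smoothed
#' potential: edge neighbors weighted 2/3, diagonal neighbors 1/6,
#'
#' `CSD = -[ (2/3) (phi_E + phi_W + phi_N + phi_S - 4 phi)
#'         + (1/6) (phi_NE + phi_NW + phi_SE + phi_SW - 4 phi) ]`.
#'
#' The stencil carries no 1/pitch^2 factor, so values are in arbitrary
#' units of uV per pitch^2; sinks are negative, sources positive.  Only
#' interior electrodes (full stencil support) are valid; the one-electrode
#' boundary ring is left NA and flagged invalid rather than padded.
#'
#' @param rec A spatially smoothed [mea_recording()] on a grid of at least
#'   3 x 3 electrodes.
#' @return An object of class `csd_volume`: list with `csd` (array shaped
#'   like the signal, NA on the boundary), `valid` (logical matrix of
#'   interior electrodes), `grid`, `sampling_rate`.
#' @export
compute_csd <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  d <- dim(rec$signal)
  if (d[1] < 3L || d[2] < 3L) {
    stop("CSD needs a grid of at least 3 x 3 electrodes", call. = FALSE)
  }
  phi <- rec$signal
  ri <- 2:(d[1] - 1L); ci <- 2:(d[2] - 1L)
  ctr <- phi[ri, ci, , drop = FALSE]
  edge <- phi[ri - 1L, ci, , drop = FALSE] + phi[ri + 1L, ci, , drop = FALSE] +
    phi[ri, ci - 1L, , drop = FALSE] + phi[ri, ci + 1L, , drop = FALSE]
  corner <- phi[ri - 1L, ci - 1L, , drop = FALSE] +
    phi[ri - 1L, ci + 1L, , drop = FALSE] +
    phi[ri + 1L, ci - 1L, , drop = FALSE] +
    phi[ri + 1L, ci + 1L, , drop = FALSE]
  lap <- (2 / 3) * (edge - 4 * ctr) + (1 / 6) * (corner - 4 * ctr)
  csd <- array(NA_real_, dim = d)
  csd[ri, ci, ] <- -lap
  valid <- matrix(FALSE, d[1], d[2])
  valid[ri, ci] <- TRUE
  structure(list(csd = csd, valid = valid, grid = rec$grid,
                 sampling_rate = rec$sampling_rate),
            class = "csd_volume")
}

#' @export
print.csd_volume <- function(x, ...) {
  cat(sprintf("<csd_volume> %s, %d frames, %d interior electrodes\n",
              format(x$grid), dim(x$csd)[3], sum(x$valid)))
  invisible(x)
}

#' Hilbert amplitude envelope of every electrode
#'
#' Computes the analytic signal of each (mean-centered) electrode trace
#' via the frequency-domain Hilbert transform and takes its modulus as
#' the dynamic amplitude `A(x, y, t)`.  Mean-centering precedes the
#' transform because a DC offset corrupts the envelope.  Per electrode the
#' temporal mean `A_bar(x, y)` and SD `xi(x, y)` (the amplitude
#' variability) are reported.
#'
#' @param rec An [mea_recording()] (low-pass filtered for LFP work).
#' @return An object of class `amplitude_field`: list with `amplitude`
#'   (array like the signal), `mean_amplitude` and `variability` (both
#'   `n_rows x n_cols` matrices), `grid`, `sampling_rate`.
#' @export
hilbert_amplitude <- function(rec) {
  stopifnot(inherits(rec, "mea_recording"))
  d <- dim(rec$signal)
  m <- matrix(rec$signal, nrow = d[1] * d[2], ncol = d[3])
  amp <- t(apply(m, 1, function(x) Mod(analytic_signal(x - mean(x)))))
  abar <- matrix(rowMeans(amp), d[1], d[2])
  xi <- matrix(apply(amp, 1, stats::sd), d[1], d[2])
  structure(list(amplitude = array(amp, dim = d),
                 mean_amplitude = abar, variability = xi,
                 grid = rec$grid, sampling_rate = rec$sampling_rate),
            class = "amplitude_field")
}

# analytic signal via the FFT construction (positive frequencies doubled)
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Select the region of interest from amplitude variability
#'
#' ROI criterion (strict inequality, exactly as specified):
#' `xi(x, y) > median(xi) + 2.326 * sd(xi)`, with median and SD taken over
#' all electrodes.  The ROI is then restricted to interior electrodes
#' (where the CSD is defined).  An empty ROI is allowed and flagged.
#'
#' @param field An `amplitude_field` from [hilbert_amplitude()].
#' @return An object of class `roi_toi`: list with `roi` (logical matrix),
#'   `threshold`, `empty` flag; `toi`, `mu_noise`, `sigma_noise` are NULL
#'   until [select_toi()] runs.
#' @export
select_roi <- function(field) {
  stopifnot(inherits(field, "amplitude_field"))
  xi <- field$variability
  thr <- stats::median(xi) + 2.326 * stats::sd(as.vector(xi))
  roi <- xi > thr
  interior <- matrix(FALSE, nrow(xi), ncol(xi))
  interior[2:(nrow(xi) - 1L), 2:(ncol(xi) - 1L)] <- TRUE
  roi <- roi & interior
  structure(list(roi = roi, threshold = thr, empty = !any(roi),
                 toi = NULL, mu_noise = NULL, sigma_noise = NULL),
            class = "roi_toi")
}

#' Select the time windows of interest within the ROI
#'
#' Noise statistics are the mean and SD, over non-ROI electrodes, of the
#' time-averaged amplitude `A_bar`.  Per ROI electrode the TOI is the set
#' of samples with `A(x, y, t) > mu_noise + 2.326 * sqrt(2) * sigma_noise`
#' (the sqrt(2) factor applied exactly as printed in the selection rule).
#'
#' @param field An `amplitude_field`.
#' @param mask A `roi_toi` from [select_roi()]; its ROI must be non-empty
#'   and must not cover the whole grid.
#' @return The `roi_toi` with `toi` (logical array, TRUE only on ROI
#'   electrodes), `mu_noise`, `sigma_noise` filled in.
#' @export
select_toi <- function(field, mask) {
  stopifnot(inherits(field, "amplitude_field"), inherits(mask, "roi_toi"))
  if (mask$empty) stop("ROI is empty; no TOI can be selected", call. = FALSE)
  if (all(mask$roi)) {
    stop("ROI covers every electrode; no noise complement exists",
         call. = FALSE)
  }
  abar <- field$mean_amplitude
  mu <- mean(abar[!mask$roi])
  sigma <- stats::sd(abar[!mask$roi])
  thr <- mu + 2.326 * sqrt(2) * sigma
  d <- dim(field$amplitude)
  toi <- array(FALSE, dim = d)
  roi_idx <- which(mask$roi, arr.ind = TRUE)
  for (k in seq_len(nrow(roi_idx))) {
    toi[roi_idx[k, 1], roi_idx[k, 2], ] <-
      field$amplitude[roi_idx[k, 1], roi_idx[k, 2], ] > thr
  }
  mask$toi <- toi
  mask$mu_noise <- mu
  mask$sigma_noise <- sigma
  mask$toi_threshold <- thr
  mask
}

#' Average rectified CSD over the ROI and TOI
#'
#' `rCSD = mean(|CSD|)` over every (ROI electrode, TOI sample) pair — the
#' per-slice scalar used for group comparison.  An empty mask yields NA
#' with a warning, never a silent zero.
#'
#' @param csd A `csd_volume` from [compute_csd()].
#' @param mask A `roi_toi` with the TOI filled in ([select_toi()]).
#' @return Scalar rCSD in arbitrary units (uV / pitch^2).
#' @export
rectified_csd <- function(csd, mask) {
  stopifnot(inherits(csd, "csd_volume"), inherits(mask, "roi_toi"))
  if (is.null(mask$toi)) stop("mask has no TOI; run select_toi() first",
                              call. = FALSE)
  sel <- mask$toi
  # only interior electrodes carry CSD values
  sel <- sel & array(csd$valid, dim = dim(sel))
  if (!any(sel)) {
    warning("empty ROI/TOI mask; rCSD undefined", call. = FALSE)
    return(NA_real_)
  }
  mean(abs(csd$csd[sel]))
}

#' Signed, sink and source CSD frames
#'
#' Extracts the CSD frame nearest each requested time and splits it into
#' its sink (negative) and source (positive) components; the two
#' components sum back to the signed frame exactly.
#'
#' @param csd A `csd_volume`.
#' @param times Numeric vector of times (s) within the recording.
#' @return A list of class `csd_frames`; element `frames` is a list with
#'   one entry per time, each holding `time_s`, `signed`, `sink`
#'   (pmin(CSD, 0)) and `source` (pmax(CSD, 0)) matrices.
#' @export
sink_source_frames <- function(csd, times) {
  stopifnot(inherits(csd, "csd_volume"))
  nt <- dim(csd$csd)[3]
  idx <- round(times * csd$sampling_rate) + 1L
  if (any(idx < 1L | idx > nt)) {
    stop("requested times fall outside the recording", call. = FALSE)
  }
  frames <- purrr::map2(times, idx, function(tt, i) {
    f <- csd$csd[, , i]
    list(time_s = tt, signed = f, sink = pmin(f, 0), source = pmax(f, 0))
  })
  structure(list(frames = frames, grid = csd$grid), class = "csd_frames")
}
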