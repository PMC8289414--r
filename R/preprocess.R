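## Movie conditioning applied before activity/coordination analysis:
## spatial smoothing, fluorescence/saturation masking, linear detrending
## (photobleaching correction) and a rigid-motion gate.

## Reflect-pad a matrix by p pixels on every side (edge row/column mirrored
## including itself, scipy-"reflect" style).
.pad_reflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(p:1, seq_len(nr), nr:(nr - p + 1L))
  ci <- c(p:1, seq_len(nc), nc:(nc - p + 1L))
  m[ri, ci]
}

## Valid-mode running mean of width k along the rows of a matrix,
## via cumulative sums.
.run_mean_rows <- function(m, k) {
  S <- rbind(0, apply(m, 2L, cumsum))
  n <- nrow(m)
  (S[(k + 1L):(n + 1L), , drop = FALSE] - S[1L:(n + 1L - k), , drop = FALSE]) / k
}

## k x k uniform (box) filter with reflect padding, separable implementation.
.box_filter <- function(m, k) {
  p <- (k - 1L) %/% 2L
  mp <- .pad_reflect(m, p)
  t(.run_mean_rows(t(.run_mean_rows(mp, k)), k))
}

#' Smooth a movie with a 5 x 5 pixel averaging filter
#'
#' Convolves every frame of every z-plane with a uniform k x k kernel
#' (default 5 x 5, the standard conditioning for islet calcium movies).
#' Borders are handled by reflect padding so edge regions are not dimmed;
#' the time axis is untouched.
#'
#' @param movie an \code{\link{islet_movie}}.
#' @param k odd kernel width in pixels (default 5).
#' @return A smoothed \code{islet_movie} of identical dimensions.
#' @export
smooth_movie <- function(movie, k = 5L) {
  stopifnot(inherits(movie, "islet_movie"))
  d <- dim(movie$data)
  if (d[3L] < k || d[4L] < k)
    stop_input("frame smaller than the smoothing kernel (", k, " x ", k, ")")
  out <- movie$data
  for (tt in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      out[tt, z, , ] <- .box_filter(matrix(movie$data[tt, z, , ], d[3L], d[4L]), k)
    }
  }
  movie$data <- out
  movie
}

#' Mask pixels without significant fluorescence or with saturation
#'
#' Excludes a pixel as \emph{saturated} if its trace ever reaches the
#' movie's saturation value, and as \emph{low fluorescence} if its temporal
#' mean falls below \code{min_mean_intensity}. The default threshold is the
#' Otsu threshold of the temporal-mean image, a parameter-free stand-in for
#' "significant fluorescence". An optional region-of-interest mask marks
#' pixels outside the islet.
#'
#' @param movie an \code{\link{islet_movie}}.
#' @param min_mean_intensity minimum temporal-mean intensity to keep a
#'   pixel; \code{NULL} (default) uses the Otsu threshold per z-plane stack
#'   of the temporal-mean image.
#' @param roi optional logical array (Z, Y, X) (or matrix (Y, X) for a
#'   single-plane movie); pixels outside are excluded with reason
#'   \code{"outside"}.
#' @return An object of class \code{pixel_mask}: list with \code{included}
#'   (logical (Z, Y, X)), \code{reason} (integer-coded array, levels
#'   \code{kept}, \code{low_fluorescence}, \code{saturated},
#'   \code{outside}) and \code{threshold}.
#' @export
mask_islet <- function(movie, min_mean_intensity = NULL, roi = NULL) {
  stopifnot(inherits(movie, "islet_movie"))
  d <- dim(movie$data)
  M <- movie_matrix(movie)
  mi <- colMeans(M)
  sat <- colSums(M >= movie$saturation_value) > 0
  dim(mi) <- d[2:4]; dim(sat) <- d[2:4]
  if (is.null(min_mean_intensity)) {
    ## Otsu threshold on the pooled temporal-mean intensities of the stack
    mx <- max(mi)
    min_mean_intensity <- if (mx <= 0) Inf else
      EBImage::otsu(EBImage::Image(matrix(as.vector(mi) / mx, ncol = 1L)),
                    range = c(0, 1), levels = 256L) * mx
  }
  if (min_mean_intensity < 0) stop_input("min_mean_intensity must be >= 0")
  reason <- array(1L, dim = d[2:4])  # 1 = kept
  reason[mi < min_mean_intensity] <- 2L  # low_fluorescence
  reason[sat] <- 3L                      # saturated
  if (!is.null(roi)) {
    if (is.matrix(roi)) roi <- array(roi, dim = c(1L, dim(roi)))
    if (!identical(dim(roi), d[2:4]))
      stop_input("roi shape must match the movie's (Z, Y, X)")
    reason[!roi] <- 4L                   # outside
  }
  structure(list(included = reason == 1L,
                 reason = structure(reason, levels = c("kept", "low_fluorescence",
                                                       "saturated", "outside")),
                 threshold = min_mean_intensity),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  tab <- table(factor(attr(x$reason, "levels")[x$reason],
                      levels = attr(x$reason, "levels")))
  cat("pixel_mask:", paste(sprintf("%s %d", names(tab), as.integer(tab)),
                           collapse = ", "),
      sprintf("(threshold %.4g)\n", x$threshold))
  invisible(x)
}

## Detrend columns of a (T, N) matrix: subtract the per-column OLS line,
## keeping the mean (the fitted line passes through the mean, so removing
## only the slope term is mean-preserving and idempotent).
.detrend_matrix <- function(M) {
  Tn <- nrow(M)
  tc <- seq_len(Tn) - (Tn + 1) / 2
  slope <- crossprod(tc, M)[1L, ] / sum(tc^2)
  M - outer(tc, slope)
}

#' Remove a linear trend (photobleaching correction)
#'
#' Fits an ordinary least-squares line to each time course and subtracts
#' it, re-adding the original mean: photobleaching over the recordings
#' analysed here is well approximated by a linear decline. Works on a
#' numeric vector, a (T x N) matrix of traces (columns), or a whole
#' \code{\link{islet_movie}} (per pixel). The operation is idempotent.
#'
#' @param x numeric vector, matrix with time down the rows, or
#'   \code{islet_movie}.
#' @return The detrended object, same shape and class as the input.
#' @export
detrend_linear <- function(x) {
  if (inherits(x, "islet_movie")) {
    d <- dim(x$data)
    if (d[1L] < 3L) stop_input("detrending needs at least 3 frames")
    M <- .detrend_matrix(movie_matrix(x))
    x$data <- array(M, dim = d)
    return(x)
  }
  if (is.matrix(x)) {
    if (nrow(x) < 3L) stop_input("detrending needs at least 3 time points")
    return(.detrend_matrix(x))
  }
  if (length(x) < 3L) stop_input("detrending needs at least 3 time points")
  drop(.detrend_matrix(matrix(x, ncol = 1L)))
}

#' Gate a movie on rigid motion
#'
#' Estimates a per-frame rigid displacement against the first frame by
#' FFT cross-correlation (integer-pixel registration on the z-averaged
#' image) and shortens the recording to the time over which no significant
#' movement occurred: the first frame displaced by at least half a cell
#' width triggers a trim at the preceding frame. A trim that leaves fewer
#' than \code{min_frames} frames rejects the movie.
#'
#' @param movie an \code{\link{islet_movie}}.
#' @param cell_width_um cell width in micrometres (displacement threshold
#'   is 0.5 x this).
#' @param min_frames minimum usable length after trimming (default 10).
#' @return list with \code{status} ("pass", "trim" or "reject"),
#'   \code{t_end} (number of retained frames; equals \code{n_frames} on
#'   pass) and \code{displacement_um} (per-frame Euclidean displacement).
#' @export
assess_motion <- function(movie, cell_width_um, min_frames = 10L) {
  stopifnot(inherits(movie, "islet_movie"))
  if (cell_width_um <= 0) stop_input("cell_width_um must be > 0")
  d <- dim(movie$data)
  Tn <- d[1L]
  ## z-averaged frames
  zavg <- function(tt) {
    if (d[2L] == 1L) matrix(movie$data[tt, 1L, , ], d[3L], d[4L])
    else apply(movie$data[tt, , , , drop = FALSE], c(3L, 4L), mean)
  }
  ref <- zavg(1L)
  F0 <- stats::fft(ref)
  disp <- numeric(Tn)
  for (tt in 2:Tn) {
    Ck <- stats::fft(zavg(tt)) * Conj(F0)
    cc <- Re(stats::fft(Ck, inverse = TRUE))
    idx <- which.max(cc) - 1L
    dy <- idx %% d[3L]
    dx <- idx %/% d[3L]
    if (dy > d[3L] / 2) dy <- dy - d[3L]
    if (dx > d[4L] / 2) dx <- dx - d[4L]
    disp[tt] <- sqrt(dy^2 + dx^2) * movie$pixel_size_um
  }
  thr <- 0.5 * cell_width_um
  bad <- which(disp >= thr)
  if (length(bad) == 0L) {
    return(list(status = "pass", t_end = Tn, displacement_um = disp))
  }
  t_end <- bad[1L] - 1L
  if (t_end < min_frames) {
    return(list(status = "reject", t_end = t_end, displacement_um = disp))
  }
  list(status = "trim", t_end = t_end, displacement_um = disp)
}

#' Trim a movie to its first \code{t_end} frames
#' @param movie an \code{islet_movie}.
#' @param t_end number of frames to keep.
#' @return The trimmed movie.
#' @export
trim_movie <- function(movie, t_end) {
  stopifnot(inherits(movie, "islet_movie"))
  if (t_end < 2L || t_end > n_frames(movie)) stop_input("invalid t_end")
  movie$data <- movie$data[seq_len(t_end), , , , drop = FALSE]
  movie
}
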