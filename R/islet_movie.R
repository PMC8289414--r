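#' Time-lapse fluorescence movie of an islet
#'
#' Container for a 4-D fluorescence record with acquisition metadata. The
#' data array is ordered (time, z, y, x); intensities are arbitrary detector
#' units with a known saturation ceiling.
#'
#' @param data numeric 4-D array with dimensions (T, Z, Y, X), T >= 2.
#' @param frame_interval_s time between frames in seconds (> 0). Recordings
#'   of islet calcium are typically taken at 1, 0.2, 0.1 or 0.03 Hz.
#' @param pixel_size_um lateral pixel size in micrometres (> 0).
#' @param saturation_value intensity at which the detector saturates;
#'   pixels that ever reach it are excluded from analysis.
#' @param z_spacing_um spacing between z-planes in micrometres.
#'
#' @return An object of class \code{islet_movie}: a list with elements
#'   \code{data}, \code{frame_interval_s}, \code{pixel_size_um},
#'   \code{saturation_value}, \code{z_spacing_um}.
#' @export
islet_movie <- function(data, frame_interval_s, pixel_size_um,
                        saturation_value = Inf, z_spacing_um = 8) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_input("movie data must be a 4-D array (T, Z, Y, X)")
  if (dim(data)[1L] < 2L)
    stop_input("movie must have at least 2 frames")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop_input("frame_interval_s must be > 0")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_input("pixel_size_um must be > 0")
  structure(list(data = data,
                 frame_interval_s = as.numeric(frame_interval_s),
                 pixel_size_um = as.numeric(pixel_size_um),
                 saturation_value = as.numeric(saturation_value),
                 z_spacing_um = as.numeric(z_spacing_um)),
            class = "islet_movie")
}

#' @export
print.islet_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("islet_movie: %d frames x %d z-planes x %d x %d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  frame interval %.3g s (%.3g Hz), pixel %.3g um, saturation %.4g\n",
              x$frame_interval_s, 1 / x$frame_interval_s,
              x$pixel_size_um, x$saturation_value))
  invisible(x)
}

#' @export
dim.islet_movie <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[1L]
n_planes <- function(movie) dim(movie$data)[2L]

## (T, Z*Y*X) matrix view of the movie; columns iterate z fastest, then y, x,
## matching the array's column-major layout.
movie_matrix <- function(movie) {
  d <- dim(movie$data)
  matrix(movie$data, nrow = d[1L])
}
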