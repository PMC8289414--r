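## Glucose-analog perfusion kinetics: bolus arrival detection on the image
## average, near/far ROI classification against the vessel mask, F/F_max
## normalization over a -5..+10 s window around arrival, AUC and
## across-ROI dispersion.

#' Detect the bolus arrival frame
#'
#' First frame whose image-average intensity rises by strictly more than
#' \code{threshold} units over the previous frame. Frame indices are
#' 0-based so that index times the frame interval is the arrival time.
#'
#' @param x an \code{\link{islet_movie}} or a numeric image-average series.
#' @param threshold intensity increase defining arrival (default 5, in the
#'   raw units of the recording).
#' @return 0-based frame index.
#' @export
detect_arrival_frame <- function(x, threshold = 5) {
  s <- if (inherits(x, "islet_movie")) rowMeans(movie_matrix(x)) else as.numeric(x)
  if (length(s) < 2L) stop_input("need at least 2 frames")
  jump <- which(diff(s) > threshold)
  if (length(jump) == 0L)
    stop(structure(class = c("isletsync_no_arrival", "error", "condition"),
                   list(message = "no arrival: image average never rises by more than the threshold",
                        call = sys.call(-1))))
  jump[1L]  # diff index i corresponds to 0-based frame i
}

#' Classify ROIs by distance from the nearest vessel
#'
#' Euclidean distance-transform distance from the ROI center to the
#' nearest vessel pixel; centers at most 10 um away are "near", the rest
#' "far" (the 10 um boundary is assigned near).
#'
#' @param rois data.frame with ROI centers \code{cy}, \code{cx} (pixels,
#'   1-based).
#' @param vessel_mask logical (Y x X) vessel mask.
#' @param pixel_size_um pixel size.
#' @param near_um near/far boundary (default 10 um).
#' @return the rois data.frame with added \code{distance_um} and
#'   \code{distance_class} ("near"/"far") columns.
#' @export
classify_rois <- function(rois, vessel_mask, pixel_size_um, near_um = 10) {
  if (!any(vessel_mask)) stop_input("empty vessel mask")
  d <- .distance_to_mask(vessel_mask) * pixel_size_um
  idx <- cbind(round(rois$cy), round(rois$cx))
  rois$distance_um <- d[idx]
  rois$distance_class <- ifelse(rois$distance_um <= near_um, "near", "far")
  rois
}

#' Randomly place circular ROIs stratified by distance class
#'
#' Samples \code{n_per_class} ROI centers per distance class from pixels
#' inside the islet-ish field (away from the image border), using the
#' distance transform from the vessel mask.
#'
#' @param vessel_mask logical (Y x X).
#' @param pixel_size_um pixel size.
#' @param n_per_class ROIs per class (default 10).
#' @param seed RNG seed.
#' @param near_um class boundary (default 10).
#' @param diameter_um ROI diameter (default 5).
#' @return data.frame: roi_id, cy, cx, distance_um, distance_class.
#' @export
place_rois <- function(vessel_mask, pixel_size_um, n_per_class = 10L,
                       seed = 1L, near_um = 10, diameter_um = 5) {
  if (!any(vessel_mask)) stop_input("empty vessel mask")
  with_seed(seed, {
    d <- .distance_to_mask(vessel_mask) * pixel_size_um
    r_px <- ceiling(diameter_um / 2 / pixel_size_um) + 1L
    ok <- matrix(TRUE, nrow(d), ncol(d))
    ok[c(seq_len(r_px), nrow(d) - seq_len(r_px) + 1L), ] <- FALSE
    ok[, c(seq_len(r_px), ncol(d) - seq_len(r_px) + 1L)] <- FALSE
    near_idx <- which(ok & d > 0 & d <= near_um)
    far_idx <- which(ok & d > near_um)
    if (length(near_idx) < n_per_class || length(far_idx) < n_per_class)
      stop_input("not enough candidate pixels for the requested ROIs")
    pick <- c(sample(near_idx, n_per_class), sample(far_idx, n_per_class))
    yx <- arrayInd(pick, dim(d))
    data.frame(roi_id = seq_along(pick), cy = yx[, 1L], cx = yx[, 2L],
               distance_um = d[pick],
               distance_class = rep(c("near", "far"), each = n_per_class))
  })
}

#' Mean-intensity time courses of circular ROIs
#'
#' @param movie an \code{\link{islet_movie}} (single plane used: z = 1).
#' @param rois data.frame with \code{cy}, \code{cx} centers (pixels).
#' @param diameter_um ROI diameter (default 5 um).
#' @return matrix (n_rois x T) of mean intensities.
#' @export
roi_traces <- function(movie, rois, diameter_um = 5) {
  stopifnot(inherits(movie, "islet_movie"))
  d <- dim(movie$data)
  M <- matrix(movie$data[, 1L, , ], d[1L], d[3L] * d[4L])
  r_px <- diameter_um / 2 / movie$pixel_size_um
  yy <- matrix(seq_len(d[3L]), d[3L], d[4L])
  xx <- matrix(seq_len(d[4L]), d[3L], d[4L], byrow = TRUE)
  out <- matrix(0, nrow(rois), d[1L])
  for (k in seq_len(nrow(rois))) {
    inside <- which((yy - rois$cy[k])^2 + (xx - rois$cx[k])^2 <= r_px^2)
    if (length(inside) == 0L)
      inside <- (round(rois$cx[k]) - 1L) * d[3L] + round(rois$cy[k])
    out[k, ] <- rowMeans(M[, inside, drop = FALSE])
  }
  out
}

#' F/F_max normalization over the arrival window
#'
#' Subtracts the minimum intensity over the window from each time point
#' and divides by (max - min), so the normalized trace attains exactly 0
#' and 1 within the window. The operation is invariant to affine rescaling
#' of the input.
#'
#' @param trace intensity values over the analysis window.
#' @return normalized trace in [0, 1].
#' @export
normalize_fmax <- function(trace) {
  mn <- min(trace); mx <- max(trace)
  if (mx <= mn) stop_input("degenerate normalization: constant trace over the window")
  (trace - mn) / (mx - mn)
}

#' Extract the -5..+10 s window around arrival from a trace
#'
#' @param trace full ROI intensity series.
#' @param arrival_frame 0-based arrival frame
#'   (\code{\link{detect_arrival_frame}}).
#' @param frame_interval_s frame interval (default 1 s; the window then
#'   spans 16 samples).
#' @param pre_s,post_s window extent (defaults -5 and +10 s).
#' @return the windowed trace, with attribute \code{time_s} of offsets
#'   relative to arrival.
#' @export
perfusion_window <- function(trace, arrival_frame, frame_interval_s = 1,
                             pre_s = 5, post_s = 10) {
  i0 <- arrival_frame + 1L  # to 1-based
  lo <- i0 - round(pre_s / frame_interval_s)
  hi <- i0 + round(post_s / frame_interval_s)
  if (lo < 1L || hi > length(trace))
    stop_input("arrival window extends outside the recording")
  w <- trace[lo:hi]
  attr(w, "time_s") <- (seq(lo, hi) - i0) * frame_interval_s
  w
}

#' Area under the normalized perfusion curve
#'
#' Trapezoidal integral of the normalized trace over the -5..+10 s window.
#'
#' @param normalized normalized window trace.
#' @param dt sample spacing in seconds (default 1).
#' @return AUC in seconds (in [0, 15] for a 15 s window).
#' @export
auc_window <- function(normalized, dt = 1) {
  pracma::trapz(seq(0, by = dt, length.out = length(normalized)), normalized)
}

#' Dispersion of normalized perfusion across ROIs at a fixed time
#'
#' Sample standard deviation across ROIs of the normalized intensity at
#' \code{t_s} seconds after arrival (default +3 s), a measure of perfusion
#' heterogeneity within the islet.
#'
#' @param normalized_traces matrix (n_rois x window length) of normalized
#'   window traces (window starting at -\code{pre_s}).
#' @param t_s evaluation time relative to arrival (default 3).
#' @param dt sample spacing (default 1 s).
#' @param pre_s window lead time (default 5 s).
#' @return standard deviation across ROIs.
#' @export
dispersion_at <- function(normalized_traces, t_s = 3, dt = 1, pre_s = 5) {
  if (nrow(normalized_traces) < 2L) stop_input("need at least 2 ROIs")
  j <- round((pre_s + t_s) / dt) + 1L
  if (j < 1L || j > ncol(normalized_traces)) stop_input("t_s outside the window")
  stats::sd(normalized_traces[, j])
}

#' Full perfusion analysis of a movie
#'
#' Detects arrival on the image average, places (or takes) ROIs, classifies
#' them near/far against the vessel mask, normalizes each ROI over the
#' arrival window, and summarizes per class: mean normalized trace, AUC of
#' the class-mean trace, and the across-ROI standard deviation at +3 s.
#'
#' @param movie perfusion \code{\link{islet_movie}} (1 Hz single plane).
#' @param vessel_mask logical (Y x X).
#' @param rois optional ROI table (\code{cy}, \code{cx}); placed randomly
#'   when NULL.
#' @param n_per_class ROIs per class for auto placement.
#' @param seed seed for ROI placement.
#' @return list with \code{arrival_frame}, \code{rois}, \code{normalized}
#'   (matrix), and per-class \code{summary} (data.frame: class, n_rois,
#'   auc, sd_at_3s, half_rise_s).
#' @export
analyze_perfusion <- function(movie, vessel_mask, rois = NULL,
                              n_per_class = 10L, seed = 1L) {
  arrival <- detect_arrival_frame(movie)
  if (is.null(rois))
    rois <- place_rois(vessel_mask, movie$pixel_size_um,
                       n_per_class = n_per_class, seed = seed)
  rois <- classify_rois(rois, vessel_mask, movie$pixel_size_um)
  tr <- roi_traces(movie, rois)
  win <- t(apply(tr, 1L, perfusion_window, arrival_frame = arrival,
                 frame_interval_s = movie$frame_interval_s))
  norm <- t(apply(win, 1L, normalize_fmax))
  classes <- unique(rois$distance_class)
  summ <- do.call(rbind, lapply(classes, function(cl) {
    sel <- rois$distance_class == cl
    m <- colMeans(norm[sel, , drop = FALSE])
    data.frame(class = cl, n_rois = sum(sel),
               auc = auc_window(m, dt = movie$frame_interval_s),
               sd_at_3s = if (sum(sel) >= 2L)
                 dispersion_at(norm[sel, , drop = FALSE]) else NA_real_,
               half_rise_s = .half_rise(m, movie$frame_interval_s),
               stringsAsFactors = FALSE)
  }))
  list(arrival_frame = arrival, rois = rois, normalized = norm,
       summary = summ)
}

## Time (s, relative to window start) at which a normalized trace first
## crosses 0.5, linearly interpolated.
.half_rise <- function(m, dt) {
  i <- which(m >= 0.5)[1L]
  if (is.na(i) || i == 1L) return((i %||% NA_integer_ - 1) * dt)
  frac <- (0.5 - m[i - 1L]) / (m[i] - m[i - 1L])
  (i - 2L + frac) * dt
}
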