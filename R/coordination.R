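## Activity classification and coordinated-area segmentation.
##
## A pixel is "active" when its (detrended) time course carries a peak with
## amplitude more than 1.5x the background noise scale. 5 x 5 pixel blocks
## tile the masked area; blocks whose mean traces correlate above 0.7 are
## merged (transitively) into coordinated regions, and the coordinated
## fraction is the pixel share of the largest region among active pixels.

#' Detect peaks in a calcium time course
#'
#' Peaks are local maxima with topographic prominence at least twice the
#' expected peak amplitude of a pure-noise trace of the same length,
#' separated by more than two frames (the higher peak wins when two maxima
#' fall closer). The per-sample noise scale is 1.4826 x MAD of the
#' first-differenced trace divided by sqrt(2) (the first difference of
#' white noise has twice the variance of the noise itself); thresholding
#' prominence against the noise scale alone would pass the chance extremes
#' that any noise trace exhibits, so the threshold is referred to the
#' expected noise extreme instead. The amplitude of a peak is its height
#' above the trace's 10th percentile baseline.
#'
#' @param trace numeric time course (detrended; length >= 10).
#' @param frame_interval_s frame interval in seconds (for reported times).
#' @return data.frame with columns \code{index} (1-based frame),
#'   \code{time_s}, \code{value}, \code{amplitude}, plus attributes
#'   \code{background} (noise scale) and \code{baseline}. Zero rows for a
#'   flat trace.
#' @export
detect_peaks <- function(trace, frame_interval_s = 1) {
  Tn <- length(trace)
  if (Tn < 10L) stop_input("peak detection needs at least 10 frames")
  empty <- data.frame(index = integer(), time_s = numeric(),
                      value = numeric(), amplitude = numeric())
  noise <- stats::mad(diff(trace)) / sqrt(2)
  baseline <- stats::quantile(trace, 0.10, names = FALSE)
  attr(empty, "background") <- noise
  attr(empty, "baseline") <- baseline
  if (max(trace) == min(trace)) return(empty)
  x <- trace
  cand <- which(x[2:(Tn - 1L)] > x[1:(Tn - 2L)] &
                x[2:(Tn - 1L)] >= x[3:Tn]) + 1L
  if (length(cand) == 0L) return(empty)
  prom <- vapply(cand, function(i) .prominence(x, i), numeric(1))
  keep <- cand[prom >= 2 * noise * .noise_peak_amplitude(Tn)]
  if (length(keep) == 0L) return(empty)
  ## enforce minimum separation: highest first, drop maxima within 2 frames
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) {
    if (all(abs(sel - i) > 2L)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  out <- data.frame(index = sel,
                    time_s = (sel - 1L) * frame_interval_s,
                    value = x[sel],
                    amplitude = x[sel] - baseline)
  attr(out, "background") <- noise
  attr(out, "baseline") <- baseline
  out
}

## Topographic prominence of the local maximum at index i: height above the
## higher of the two key saddles (minima toward the nearest higher ground,
## or toward the trace ends).
.prominence <- function(x, i) {
  n <- length(x)
  left <- if (i == 1L) x[i] else {
    j <- i - 1L; lo <- x[j]
    while (j >= 1L && x[j] <= x[i]) { lo <- min(lo, x[j]); j <- j - 1L }
    lo
  }
  right <- if (i == n) x[i] else {
    j <- i + 1L; lo <- x[j]
    while (j <= n && x[j] <= x[i]) { lo <- min(lo, x[j]); j <- j + 1L }
    lo
  }
  x[i] - max(left, right)
}

#' Classify a time course as active
#'
#' A region is active when its maximum peak amplitude exceeds 1.5x the
#' background noise scale (strict inequality).
#'
#' @param peaks peak table from \code{\link{detect_peaks}}.
#' @param background background noise scale (> 0); defaults to the
#'   \code{background} attribute of \code{peaks}.
#' @param factor amplitude multiple required for activity (default 1.5).
#' @return logical.
#' @export
classify_active <- function(peaks, background = attr(peaks, "background"),
                            factor = 1.5) {
  if (is.null(background) || !is.numeric(background) || background <= 0)
    stop_input("background must be > 0")
  nrow(peaks) > 0 && max(peaks$amplitude) > factor * background
}

## Vectorized activity call over columns of a (T, N) trace matrix. The
## "background" against which the 1.5x amplitude rule is applied is the
## expected peak amplitude (maximum minus 10th-percentile baseline) of a
## pure-noise trace of the same length -- the raw noise sigma alone would
## flag noise-only traces, whose extremes always exceed 1.5 sigma.
.pixel_activity <- function(M, factor = 1.5) {
  Tn <- nrow(M)
  D <- M[-1L, , drop = FALSE] - M[-Tn, , drop = FALSE]
  dmad <- .col_quantile(abs(sweep(D, 2L, .col_quantile(D, 0.5), "-")), 0.5)
  noise <- 1.4826 * dmad / sqrt(2)
  amp <- .col_max(M) - .col_quantile(M, 0.10)
  background <- noise * .noise_peak_amplitude(Tn)
  noise > 0 & amp > factor * background
}

## Expected peak amplitude (max - 10th percentile), in units of sigma, of a
## white-noise trace of length T.
.noise_peak_amplitude <- function(Tn) {
  stats::qnorm(Tn / (Tn + 1)) + stats::qnorm(0.9)
}

## Column-wise max via pmax over rows (avoids per-column apply overhead).
.col_max <- function(M) do.call(pmax, lapply(seq_len(nrow(M)), function(i) M[i, ]))

## Column-wise type-7 quantile via full sort of each column (one matrix sort).
.col_quantile <- function(M, p) {
  S <- apply(M, 2L, sort.int, method = "quick")
  n <- nrow(M)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  S[lo, ] + (h - lo) * (S[hi, ] - S[lo, ])
}

#' Tile the masked area into 5 x 5 pixel block traces
#'
#' Blocks tile each z-plane in \code{block} x \code{block} pixel tiles; a
#' tile enters the set when a majority of its pixels (>= 13 of 25 by
#' default) are kept by the mask. The block trace is the mean time course
#' over kept pixels.
#'
#' @param movie a (smoothed, detrended) \code{\link{islet_movie}}.
#' @param mask a \code{pixel_mask} from \code{\link{mask_islet}}.
#' @param block tile width in pixels (default 5).
#' @param min_block_pixels minimum kept pixels per tile (default 13).
#' @param active_pixels optional logical (Z, Y, X) per-pixel activity map;
#'   computed from the movie when NULL.
#' @return An object of class \code{block_trace_set}: list with
#'   \code{info} (data.frame: block_id, z, cy, cx (pixel centroids),
#'   n_pixels_kept, n_active_pixels, active) and \code{traces}
#'   (T x n_blocks matrix).
#' @export
block_traces <- function(movie, mask, block = 5L, min_block_pixels = 13L,
                         active_pixels = NULL) {
  stopifnot(inherits(movie, "islet_movie"), inherits(mask, "pixel_mask"))
  d <- dim(movie$data)
  if (is.null(active_pixels)) {
    active_pixels <- array(FALSE, dim = d[2:4])
    keep <- which(mask$included)
    M <- movie_matrix(movie)
    active_pixels[keep] <- .pixel_activity(M[, keep, drop = FALSE])
  }
  info <- list(); traces <- list(); bid <- 0L
  for (z in seq_len(d[2L])) {
    inc <- matrix(mask$included[z, , ], d[3L], d[4L])
    act <- matrix(active_pixels[z, , ], d[3L], d[4L])
    by <- seq(1L, d[3L] - block + 1L, by = block)
    bx <- seq(1L, d[4L] - block + 1L, by = block)
    for (y0 in by) for (x0 in bx) {
      yy <- y0:(y0 + block - 1L); xx <- x0:(x0 + block - 1L)
      sub <- inc[yy, xx]
      nk <- sum(sub)
      if (nk < min_block_pixels) next
      bid <- bid + 1L
      blockdat <- movie$data[, z, yy, xx, drop = FALSE]
      dim(blockdat) <- c(d[1L], block * block)
      tr <- rowMeans(blockdat[, as.vector(sub), drop = FALSE])
      info[[bid]] <- data.frame(block_id = bid, z = z,
                                cy = mean(yy), cx = mean(xx),
                                n_pixels_kept = nk,
                                n_active_pixels = sum(act[yy, xx] & sub))
      traces[[bid]] <- tr
    }
  }
  if (bid == 0L) stop_undefined("no blocks satisfy the mask majority rule")
  info <- do.call(rbind, info)
  traces <- do.call(cbind, traces)
  colnames(traces) <- info$block_id
  info$active <- .pixel_activity(traces) & info$n_active_pixels > 0
  structure(list(info = info, traces = traces,
                 active_pixel_map = active_pixels,
                 n_kept_pixels = sum(mask$included),
                 n_active_pixels_total = sum(active_pixels)),
            class = "block_trace_set")
}

#' Merge coordinated blocks into regions
#'
#' Computes zero-lag Pearson correlations between active block traces and
#' merges blocks whose correlation exceeds \code{r_min} (strict), taking
#' the transitive closure: regions are the connected components of the
#' correlation-threshold graph restricted to active blocks. Spatial
#' contiguity is not required (synchronized regions may be non-contiguous
#' across the islet); set \code{require_contiguity = TRUE} to additionally
#' demand tile adjacency within a region. Peak-coincidence co-seeding
#' (two blocks with at least half of their peaks aligned within one frame)
#' is reported as a diagnostic alongside the partition.
#'
#' @param blocks a \code{block_trace_set}.
#' @param r_min correlation threshold (default 0.7).
#' @param require_contiguity require tile adjacency within regions.
#' @param report_seeds also compute the peak-coincidence co-seeding table
#'   (slower; default FALSE). Available separately via
#'   \code{\link{peak_coincidence_pairs}}.
#' @return An object of class \code{coordination_map}: the block table with
#'   a \code{region_label} column (0 = uncoordinated/inactive; labels
#'   ordered by active-pixel count, largest = 1), per-region pixel counts,
#'   the active-pixel map, and the activity/coordination fractions.
#' @export
merge_coordinated <- function(blocks, r_min = 0.7, require_contiguity = FALSE,
                              report_seeds = FALSE) {
  stopifnot(inherits(blocks, "block_trace_set"))
  info <- blocks$info
  act <- which(info$active)
  label <- integer(nrow(info))
  if (length(act) < 2L) {
    warning("fewer than 2 active blocks; coordination is trivial")
    if (length(act) == 1L) label[act] <- 1L
  } else {
    tr <- blocks$traces[, act, drop = FALSE]
    R <- suppressWarnings(stats::cor(tr))
    R[is.na(R)] <- 0
    A <- R > r_min
    diag(A) <- FALSE
    if (require_contiguity) {
      adj <- .block_adjacency(info[act, ])
      A <- A & adj
    }
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    comp <- igraph::components(g)$membership
    ## order region labels by active-pixel count, descending (ties: lower
    ## original label first)
    sizes <- tapply(info$n_active_pixels[act], comp, sum)
    ord <- order(-as.numeric(sizes), as.numeric(names(sizes)))
    relab <- integer(length(sizes))
    relab[as.integer(names(sizes))[ord]] <- seq_along(ord)
    label[act] <- relab[comp]
  }
  info$region_label <- label
  npx <- tapply(info$n_active_pixels[label > 0], label[label > 0], sum)
  region_pixels <- as.numeric(npx)[order(as.integer(names(npx)))]
  structure(list(blocks = info,
                 region_pixels = region_pixels,
                 active_pixel_map = blocks$active_pixel_map,
                 n_kept_pixels = blocks$n_kept_pixels,
                 n_active_pixels_total = blocks$n_active_pixels_total,
                 r_min = r_min,
                 seed_pairs = if (report_seeds) peak_coincidence_pairs(blocks)),
            class = "coordination_map")
}

## Tile adjacency (4-neighborhood in block coordinates, same z).
.block_adjacency <- function(info) {
  n <- nrow(info)
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    A[i, j] <- A[j, i] <-
      info$z[i] == info$z[j] &&
      (abs(info$cy[i] - info$cy[j]) + abs(info$cx[i] - info$cx[j])) <= 5
  }
  A
}

#' Peak-coincidence co-seeding pairs
#'
#' Diagnostic companion to \code{\link{merge_coordinated}}: pairs of
#' active blocks whose identified peaks coincide (at least 50% of the
#' smaller peak set aligned within one frame), the coincident-timing
#' criterion that seeds region formation.
#'
#' @param blocks a \code{block_trace_set}.
#' @return data.frame of block-id pairs (i, j).
#' @export
peak_coincidence_pairs <- function(blocks) {
  act <- which(blocks$info$active)
  if (length(act) < 2L) return(data.frame(i = integer(), j = integer()))
  pk <- lapply(act, function(b) detect_peaks(blocks$traces[, b])$index)
  out <- list(); k <- 0L
  for (ii in seq_along(act)[-length(act)]) {
    for (jj in (ii + 1L):length(act)) {
      a <- pk[[ii]]; b <- pk[[jj]]
      if (length(a) == 0L || length(b) == 0L) next
      hits <- sum(vapply(a, function(p) any(abs(b - p) <= 1L), logical(1)))
      if (hits / min(length(a), length(b)) >= 0.5) {
        k <- k + 1L
        out[[k]] <- data.frame(i = act[ii], j = act[jj])
      }
    }
  }
  if (k == 0L) data.frame(i = integer(), j = integer()) else do.call(rbind, out)
}

#' Fraction of the islet that is active
#'
#' Number of active pixels across all z-planes divided by the number of
#' kept (significant-fluorescence, non-saturated) pixels across all
#' z-planes.
#'
#' @param map a \code{coordination_map}.
#' @return numeric in [0, 1].
#' @export
active_fraction <- function(map) {
  stopifnot(inherits(map, "coordination_map"))
  if (map$n_kept_pixels == 0L) stop_undefined("no kept pixels")
  map$n_active_pixels_total / map$n_kept_pixels
}

#' Fraction of active area in the largest coordinated region
#'
#' Active pixels of the largest coordinated region, aggregated across
#' z-planes, divided by all active pixels within the analysis blocks.
#'
#' @param map a \code{coordination_map}.
#' @return numeric in (0, 1].
#' @export
largest_coordinated_fraction <- function(map) {
  stopifnot(inherits(map, "coordination_map"))
  act_in_blocks <- sum(map$blocks$n_active_pixels[map$blocks$active])
  if (length(map$region_pixels) == 0L || act_in_blocks == 0)
    stop_undefined("no active pixels")
  map$region_pixels[1L] / act_in_blocks
}

#' Number of major coordinated regions
#'
#' Regions holding at least \code{min_share} of the active area (default
#' 10%), the statistic used to recover the number of synchronization
#' domains.
#'
#' @param map a \code{coordination_map}.
#' @param min_share minimum share of active pixels (default 0.1).
#' @return integer count.
#' @export
n_major_regions <- function(map, min_share = 0.10) {
  stopifnot(inherits(map, "coordination_map"))
  act <- sum(map$blocks$n_active_pixels[map$blocks$active])
  if (act == 0) return(0L)
  sum(map$region_pixels / act >= min_share)
}

#' Activity and coordination analysis of a conditioned movie
#'
#' Convenience wrapper: per-pixel activity on kept pixels, block tiling,
#' coordinated-region merging, and the activity/coordination fractions.
#' The movie should already be smoothed and detrended (see
#' \code{\link{smooth_movie}}, \code{\link{detrend_linear}}).
#'
#' @param movie conditioned \code{\link{islet_movie}}.
#' @param mask a \code{pixel_mask}; computed with defaults when NULL.
#' @param r_min merge correlation threshold (default 0.7).
#' @param ... passed to \code{\link{block_traces}}.
#' @return A \code{coordination_map} (see \code{\link{merge_coordinated}})
#'   with an added \code{fractions} element.
#' @export
coordination_map <- function(movie, mask = NULL, r_min = 0.7, ...) {
  if (is.null(mask)) mask <- mask_islet(movie)
  blocks <- block_traces(movie, mask, ...)
  map <- merge_coordinated(blocks, r_min = r_min)
  map$fractions <- list(
    active_fraction = active_fraction(map),
    largest_coordinated_fraction =
      if (length(map$region_pixels)) largest_coordinated_fraction(map) else NA_real_)
  map
}

#' @export
print.coordination_map <- function(x, ...) {
  cat(sprintf("coordination_map: %d blocks (%d active), %d regions, r_min %.2f\n",
              nrow(x$blocks), sum(x$blocks$active),
              length(x$region_pixels), x$r_min))
  if (!is.null(x$fractions))
    cat(sprintf("  active fraction %.3f, largest coordinated fraction %.3f\n",
                x$fractions$active_fraction,
                x$fractions$largest_coordinated_fraction))
  invisible(x)
}
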