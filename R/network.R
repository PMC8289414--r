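## Thresholded functional networks from per-cell calcium traces, and the
## hub / clustering / path-length / efficiency metrics computed on them.
## The clustering coefficient here follows the analysis it reproduces:
## C_i = degree_i / (n - 1), i.e. normalized degree (no constraint on
## "possible connections"), with conventional transitivity available as an
## alternative. Characteristic path length and global efficiency both use
## the fixed denominator n * (n - 1) regardless of reachability.

#' Per-cell trace set from a movie z-plane
#'
#' Chooses the z-plane with the greatest sensor coverage and extracts one
#' mean time course per expressing cell from its footprint pixels.
#'
#' @param movie an \code{\link{islet_movie}} (ideally detrended).
#' @param truth a \code{ground_truth} (for the cell-footprint label map),
#'   or a (Y x X) integer label matrix via \code{cell_pixels}.
#' @param cell_pixels optional label matrix overriding \code{truth}.
#' @param z z-plane to use; the plane with most labeled pixels when NULL.
#' @return An object of class \code{cell_trace_set}: list with
#'   \code{traces} (n_cells x T), \code{cells} (data.frame: cell_id,
#'   cy, cx in pixels) and \code{z}.
#' @export
extract_cell_traces <- function(movie, truth = NULL, cell_pixels = NULL, z = NULL) {
  stopifnot(inherits(movie, "islet_movie"))
  lab <- cell_pixels %||% truth$cell_pixels
  if (is.null(lab)) stop_input("a cell label map is required")
  d <- dim(movie$data)
  if (is.null(z)) z <- 1L  # the label map is shared across planes here
  ids <- sort(unique(lab[lab > 0L]))
  if (!is.null(truth)) ids <- ids[truth$active_cells[ids]]
  Tn <- d[1L]
  traces <- matrix(0, length(ids), Tn)
  cells <- data.frame(cell_id = ids, cy = NA_real_, cx = NA_real_)
  M <- matrix(movie$data[, z, , ], Tn, d[3L] * d[4L])
  for (k in seq_along(ids)) {
    pix <- which(as.vector(lab) == ids[k])
    traces[k, ] <- rowMeans(M[, pix, drop = FALSE])
    yx <- arrayInd(pix, dim(lab))
    cells$cy[k] <- mean(yx[, 1L]); cells$cx[k] <- mean(yx[, 2L])
  }
  structure(list(traces = traces, cells = cells, z = z,
                 frame_interval_s = movie$frame_interval_s,
                 pixel_size_um = movie$pixel_size_um),
            class = "cell_trace_set")
}

#' Build a thresholded functional network from cell traces
#'
#' Pairwise Pearson correlation over the full-length traces; the diagonal
#' is set to zero (a cell is not considered synchronized with itself) and
#' two cells are linked when R >= R_th (0.95 for analysis; 0.98 is the
#' power-law calibration point of control recordings). Cells with constant
#' traces have undefined correlations and are excluded with a warning.
#'
#' @param traces a \code{cell_trace_set}, or an n_cells x T numeric matrix.
#' @param R_th correlation threshold (default 0.95).
#' @return An object of class \code{functional_network}: list with
#'   \code{R} (symmetric, zero diagonal), \code{A} (logical adjacency),
#'   \code{R_th}, \code{n_cells} and \code{cell_id}.
#' @export
build_adjacency <- function(traces, R_th = 0.95) {
  m <- if (inherits(traces, "cell_trace_set")) traces$traces else as.matrix(traces)
  ids <- if (inherits(traces, "cell_trace_set")) traces$cells$cell_id
         else seq_len(nrow(m))
  if (nrow(m) < 3L) stop_input("network metrics need at least 3 cells")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant trace(s) excluded (undefined correlation)")
    ids <- ids[sds > 0]
    m <- m[sds > 0, , drop = FALSE]
    if (nrow(m) < 3L) stop_input("fewer than 3 usable cells after exclusion")
  }
  R <- stats::cor(t(m))
  diag(R) <- 0
  A <- R >= R_th
  diag(A) <- FALSE
  structure(list(R = R, A = A, R_th = R_th, n_cells = nrow(m),
                 cell_id = ids),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("functional_network: %d cells, %d links at R_th = %.3g\n",
              x$n_cells, sum(x$A) / 2, x$R_th))
  invisible(x)
}

#' Calibrate the correlation threshold by power-law degree scan
#'
#' For each candidate threshold, builds the degree distribution and fits a
#' log10--log10 linear model to the occupied nonzero-degree bins; the
#' calibrated threshold is the largest candidate whose fit reaches
#' R^2 >= 0.9 over at least 5 occupied bins (control recordings show such
#' a power law at 0.98). When no candidate qualifies the scan is flagged
#' and the analysis default 0.95 is returned with a warning. Significance
#' of the links retained at the returned threshold is assessed by a
#' circular time-shift permutation null (all cyclic shifts of one trace of
#' each pair), which preserves autocorrelation.
#'
#' @param traces a \code{cell_trace_set} or n_cells x T matrix (>= 10
#'   cells).
#' @param candidates candidate thresholds (default 0.80 to 0.999).
#' @param fit_r2 fit acceptance (default 0.9).
#' @param min_bins minimum occupied degree bins (default 5).
#' @param default fallback threshold (default 0.95).
#' @param significance compute the permutation check (default TRUE).
#' @return list with \code{R_th}, \code{qualified} (logical), \code{scan}
#'   (data.frame: candidate, n_bins, r_squared, mean_degree) and, when
#'   requested, \code{link_p} (per-link permutation p-values) and
#'   \code{frac_links_p_lt_001}.
#' @export
calibrate_threshold <- function(traces, candidates = seq(0.80, 0.999, by = 0.0035),
                                fit_r2 = 0.9, min_bins = 5L, default = 0.95,
                                significance = TRUE) {
  m <- if (inherits(traces, "cell_trace_set")) traces$traces else as.matrix(traces)
  if (nrow(m) < 10L) stop_input("threshold calibration needs at least 10 cells")
  R <- stats::cor(t(m)); diag(R) <- 0
  scan <- data.frame(candidate = candidates, n_bins = NA_integer_,
                     r_squared = NA_real_, mean_degree = NA_real_)
  for (i in seq_along(candidates)) {
    A <- R >= candidates[i]; diag(A) <- FALSE
    deg <- colSums(A)
    scan$mean_degree[i] <- mean(deg)
    tab <- table(deg[deg > 0])
    scan$n_bins[i] <- length(tab)
    if (length(tab) >= 3L) {
      fit <- stats::lm(log10(as.numeric(tab)) ~ log10(as.numeric(names(tab))))
      scan$r_squared[i] <- summary(fit)$r.squared
    }
  }
  ok <- which(!is.na(scan$r_squared) & scan$r_squared >= fit_r2 &
              scan$n_bins >= min_bins)
  if (length(ok) == 0L) {
    warning("no candidate threshold shows a power-law degree distribution; ",
            "returning default ", default)
    R_th <- default; qualified <- FALSE
  } else {
    R_th <- max(candidates[ok]); qualified <- TRUE
  }
  out <- list(R_th = R_th, qualified = qualified, scan = scan)
  if (significance) {
    A <- R >= R_th; diag(A) <- FALSE
    links <- which(A & upper.tri(A), arr.ind = TRUE)
    if (nrow(links) > 0L) {
      p <- vapply(seq_len(nrow(links)), function(k)
        .circular_shift_p(m[links[k, 1L], ], m[links[k, 2L], ]), numeric(1))
      out$link_p <- p
      out$frac_links_p_lt_001 <- mean(p < 0.001)
    } else {
      out$link_p <- numeric(0)
      out$frac_links_p_lt_001 <- NA_real_
    }
  }
  out
}

## Permutation p-value of the zero-shift correlation against all circular
## shifts, computed at once by FFT cross-correlation.
.circular_shift_p <- function(x, y) {
  Tn <- length(x)
  x0 <- (x - mean(x)); y0 <- (y - mean(y))
  denom <- sqrt(sum(x0^2) * sum(y0^2))
  ## circular cross-correlation at all shifts via FFT (R's inverse fft is
  ## unnormalized, hence the 1/T)
  cc <- Re(stats::fft(stats::fft(x0) * Conj(stats::fft(y0)), inverse = TRUE)) / Tn
  r_all <- cc / denom
  mean(r_all >= r_all[1L])
}

#' Percent-links-per-cell distribution
#'
#' Per-cell links divided by (n - 1), binned into a histogram (10 bins of
#' 10% by default). Zero-degree cells are counted in the returned
#' statistics but excluded from the histogram, matching how such
#' distributions are plotted.
#'
#' @param net a \code{functional_network}.
#' @param bins number of equal-width percent bins (default 10).
#' @return list with \code{percent_links} (per cell), \code{histogram}
#'   (data.frame: bin_lo, bin_hi, count; zero-degree cells excluded),
#'   \code{mean_percent} and \code{n_zero_degree}.
#' @export
degree_distribution <- function(net, bins = 10L) {
  stopifnot(inherits(net, "functional_network"))
  deg <- colSums(net$A)
  pct <- 100 * deg / (net$n_cells - 1L)
  br <- seq(0, 100, length.out = bins + 1L)
  h <- graphics::hist(pct[deg > 0], breaks = br, plot = FALSE)
  list(percent_links = pct,
       histogram = data.frame(bin_lo = utils::head(br, -1L),
                              bin_hi = br[-1L], count = h$counts),
       mean_percent = mean(pct),
       n_zero_degree = sum(deg == 0))
}

#' Average pairwise correlation of an islet
#'
#' Mean and standard deviation of the upper-triangle entries of the
#' pairwise correlation matrix.
#'
#' @param net a \code{functional_network}.
#' @return list with \code{R_avg} and \code{R_sd}.
#' @export
mean_pairwise_correlation <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  v <- net$R[upper.tri(net$R)]
  list(R_avg = mean(v), R_sd = stats::sd(v))
}

#' Fraction of hub cells
#'
#' A hub is a cell linked to at least \code{hub_cut} (default 25%) of the
#' rest of the islet: links / (n - 1) >= hub_cut. The boundary convention
#' (>= rather than >) follows the size-invariant definition used when
#' highlighting hubs; it is configurable.
#'
#' @param net a \code{functional_network}.
#' @param hub_cut linked fraction defining a hub (default 0.25).
#' @param strict use a strict > comparison instead of >=.
#' @return fraction of cells that are hubs, in [0, 1].
#' @export
hub_fraction <- function(net, hub_cut = 0.25, strict = FALSE) {
  stopifnot(inherits(net, "functional_network"))
  frac <- colSums(net$A) / (net$n_cells - 1L)
  hubs <- if (strict) frac > hub_cut else frac >= hub_cut
  mean(hubs)
}

#' Clustering coefficient (normalized degree form)
#'
#' \code{method = "degree"} (the primary form here): C_i is the number of
#' connections of cell i divided by the number of possible connections,
#' n - 1 -- i.e. normalized degree, because no constraint is placed on
#' possible connections. \code{method = "transitivity"} gives the
#' conventional local clustering coefficient (triangle density among
#' neighbors) for comparison.
#'
#' @param net a \code{functional_network}.
#' @param method "degree" (default) or "transitivity".
#' @return list with \code{C} (per cell) and \code{C_avg}.
#' @export
clustering_coefficient <- function(net, method = c("degree", "transitivity")) {
  stopifnot(inherits(net, "functional_network"))
  method <- match.arg(method)
  if (method == "degree") {
    C <- colSums(net$A) / (net$n_cells - 1L)
  } else {
    g <- .net_graph(net)
    C <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  }
  list(C = C, C_avg = mean(C))
}

.net_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$A, mode = "undirected")
}

#' All-pairs shortest path lengths
#'
#' Unweighted breadth-first shortest paths between every pair of cells.
#' Pairs without any connecting path are marked \code{Inf} (absent) and do
#' not contribute to the path-length or efficiency sums.
#'
#' @param net a \code{functional_network}.
#' @return n x n numeric matrix of path lengths (0 diagonal, Inf for
#'   unreachable pairs).
#' @export
shortest_paths_matrix <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  igraph::distances(.net_graph(net), mode = "all")
}

#' Characteristic path length
#'
#' Sum of all finite off-diagonal path lengths over ordered pairs,
#' normalized by the total possible connections n * (n - 1) -- the
#' denominator is fixed regardless of reachability, so disconnected pairs
#' contribute zero.
#'
#' @param paths path-length matrix from \code{\link{shortest_paths_matrix}}.
#' @param n number of cells (defaults to \code{nrow(paths)}).
#' @return L_char.
#' @export
characteristic_path_length <- function(paths, n = nrow(paths)) {
  off <- row(paths) != col(paths)
  fin <- off & is.finite(paths)
  sum(paths[fin]) / (n * (n - 1L))
}

#' Global efficiency
#'
#' E_glob = (1 / (n * (n - 1))) * sum over ordered reachable pairs of
#' 1 / L(j, k); unreachable pairs contribute zero. Equals 1 exactly on a
#' complete graph.
#'
#' @param paths path-length matrix from \code{\link{shortest_paths_matrix}}.
#' @param n number of cells (defaults to \code{nrow(paths)}).
#' @return E_glob in [0, 1].
#' @export
global_efficiency <- function(paths, n = nrow(paths)) {
  off <- row(paths) != col(paths)
  fin <- off & is.finite(paths)
  sum(1 / paths[fin]) / (n * (n - 1L))
}

#' All network metrics of a functional network
#'
#' @param net a \code{functional_network}.
#' @param hub_cut hub definition (default 0.25).
#' @return list with \code{R_avg}, \code{R_sd}, \code{hub_fraction},
#'   \code{C_avg}, \code{C_avg_transitivity}, \code{L_char},
#'   \code{E_glob}, \code{mean_percent_links}, \code{n_zero_degree}.
#' @export
network_metrics <- function(net, hub_cut = 0.25) {
  rp <- mean_pairwise_correlation(net)
  dd <- degree_distribution(net)
  paths <- shortest_paths_matrix(net)
  list(R_avg = rp$R_avg, R_sd = rp$R_sd,
       hub_fraction = hub_fraction(net, hub_cut),
       C_avg = clustering_coefficient(net, "degree")$C_avg,
       C_avg_transitivity = clustering_coefficient(net, "transitivity")$C_avg,
       L_char = characteristic_path_length(paths, net$n_cells),
       E_glob = global_efficiency(paths, net$n_cells),
       mean_percent_links = dd$mean_percent,
       n_zero_degree = dd$n_zero_degree)
}
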