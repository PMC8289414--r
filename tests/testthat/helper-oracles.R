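# Independent oracles and fixture builders used across the suite.

# Floyd-Warshall all-pairs shortest paths on a logical adjacency matrix.
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Union-find partition over the edges of a logical matrix (i ~ j iff E[i,j]).
# Returns a canonical component label per node.
union_find_partition <- function(E) {
  n <- nrow(E)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (E[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Naive double-loop 5x5 mean at an interior pixel.
naive_box_mean <- function(m, y, x, k = 5L) {
  p <- (k - 1L) %/% 2L
  mean(m[(y - p):(y + p), (x - p):(x + p)])
}

# Build a functional_network object directly from a logical adjacency matrix.
net_from_adjacency <- function(A, R = NULL, R_th = 0.95) {
  n <- nrow(A)
  diag(A) <- FALSE
  if (is.null(R)) { R <- matrix(0, n, n); R[A] <- 1 }
  structure(list(R = R, A = A, R_th = R_th, n_cells = n,
                 cell_id = seq_len(n)),
            class = "functional_network")
}

# Build a block_trace_set from a (T x n) trace matrix.
blocks_from_traces <- function(traces, active = rep(TRUE, ncol(traces)),
                               n_active_pixels = rep(25L, ncol(traces)),
                               z = 1L) {
  n <- ncol(traces)
  info <- data.frame(block_id = seq_len(n), z = z,
                     cy = 5 * seq_len(n), cx = 5,
                     n_pixels_kept = 25L,
                     n_active_pixels = n_active_pixels,
                     active = active)
  structure(list(info = info, traces = traces,
                 active_pixel_map = NULL,
                 n_kept_pixels = 25L * n,
                 n_active_pixels_total = sum(n_active_pixels)),
            class = "block_trace_set")
}

# Random symmetric adjacency matrix on n nodes with edge probability p.
random_adjacency <- function(n, p) {
  A <- matrix(FALSE, n, n)
  A[upper.tri(A)] <- stats::runif(n * (n - 1) / 2) < p
  A | t(A)
}

# A small movie with every pixel sharing one of the provided traces.
movie_from_traces <- function(trace_matrix, assignment, ny, nx,
                              frame_interval_s = 1, pixel_size_um = 1,
                              saturation_value = 1e6) {
  Tn <- nrow(trace_matrix)
  data <- array(0, dim = c(Tn, 1L, ny, nx))
  data[, 1L, , ] <- trace_matrix[, as.vector(assignment)]
  islet_movie(data, frame_interval_s, pixel_size_um, saturation_value)
}
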