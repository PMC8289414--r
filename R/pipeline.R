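## File formats, run configuration and the end-to-end pipeline driver.
## Conventions: coordinates are pixel-based, origin top-left; in-file frame
## indices are 0-based (index * frame interval = time); physical units come
## from pixel_size_um. JSON holds scalars and metadata, CSV tables, TIFF
## rasters.

.VALID_KEYS <- c("seed", "out_dir", "simulate", "movie_path", "cells_path",
                 "smooth_kernel", "activity_factor", "coordination_r_min",
                 "network_r_th", "hub_cut", "coordination_gate", "rout_q",
                 "replicate_policy", "time_lag_mode", "sim")

#' Build and validate a pipeline run configuration
#'
#' All analysis thresholds carry the defaults of the reproduced analysis:
#' 5 x 5 smoothing, 1.5x background activity rule, 0.7 coordination merge
#' threshold, 0.95 network link threshold, 25% hub cut, 80% coordination
#' gate for wave analysis, ROUT Q = 0.1%. Unknown keys and out-of-range
#' thresholds are rejected before any computation.
#'
#' @param seed integer seed driving every stochastic step of the run.
#' @param out_dir output directory, or NULL for no file output.
#' @param simulate logical: generate the inputs with the synthetic islet
#'   generator (using \code{sim}) instead of reading files.
#' @param movie_path,cells_path input files when \code{simulate = FALSE}.
#' @param smooth_kernel odd smoothing kernel width (default 5).
#' @param activity_factor activity amplitude multiple (default 1.5).
#' @param coordination_r_min merge threshold (default 0.7, in [-1, 1]).
#' @param network_r_th link threshold (default 0.95, in [0, 1]).
#' @param hub_cut hub linked-fraction cut (default 0.25, in [0, 1]).
#' @param coordination_gate coordinated-fraction gate for wave analysis
#'   (default 0.80, in [0, 1]).
#' @param rout_q ROUT FDR (default 0.001, in (0, 1)).
#' @param replicate_policy "islet" (each islet a biological replicate, as
#'   for intravital oscillation metrics) or "mouse" (islets averaged per
#'   mouse, as for architecture comparisons).
#' @param time_lag_mode "as_printed" or "standard" (see
#'   \code{\link{time_lag}}).
#' @param sim list of overrides for \code{\link{simulation_config}}.
#' @return A validated list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, simulate = TRUE,
                       movie_path = NULL, cells_path = NULL,
                       smooth_kernel = 5L, activity_factor = 1.5,
                       coordination_r_min = 0.7, network_r_th = 0.95,
                       hub_cut = 0.25, coordination_gate = 0.80,
                       rout_q = 0.001,
                       replicate_policy = c("islet", "mouse"),
                       time_lag_mode = c("as_printed", "standard"),
                       sim = list()) {
  replicate_policy <- match.arg(replicate_policy)
  time_lag_mode <- match.arg(time_lag_mode)
  chk <- function(v, lo, hi, name, open = FALSE) {
    bad <- if (open) v <= lo || v >= hi else v < lo || v > hi
    if (!is.numeric(v) || bad)
      stop_config(name, " = ", v, " outside its valid range [", lo, ", ", hi, "]")
  }
  if (smooth_kernel < 1L || smooth_kernel %% 2L != 1L)
    stop_config("smooth_kernel must be odd and >= 1")
  if (activity_factor <= 0) stop_config("activity_factor must be > 0")
  chk(coordination_r_min, -1, 1, "coordination_r_min")
  chk(network_r_th, 0, 1, "network_r_th")
  chk(hub_cut, 0, 1, "hub_cut")
  chk(coordination_gate, 0, 1, "coordination_gate")
  chk(rout_q, 0, 1, "rout_q", open = TRUE)
  if (length(setdiff(names(sim), names(formals(simulation_config)))) > 0L)
    stop_config("unknown simulation keys: ",
                paste(setdiff(names(sim), names(formals(simulation_config))),
                      collapse = ", "))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, movie_path = movie_path,
                 cells_path = cells_path, smooth_kernel = as.integer(smooth_kernel),
                 activity_factor = activity_factor,
                 coordination_r_min = coordination_r_min,
                 network_r_th = network_r_th, hub_cut = hub_cut,
                 coordination_gate = coordination_gate, rout_q = rout_q,
                 replicate_policy = replicate_policy,
                 time_lag_mode = time_lag_mode, sim = sim),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; values are validated by
#' \code{\link{run_config}}.
#'
#' @param path .yaml/.yml or .json file.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .VALID_KEYS)
  if (length(unknown) > 0L)
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) the inputs, condition the movie (smooth, mask,
#' detrend, motion gate), run activity/coordination analysis, wave
#' phase-lag analysis, functional-network metrics and (when an
#' architecture is available) contact probabilities, then write versioned
#' JSON/CSV results and a reproducibility manifest. Identical config and
#' seed give byte-identical result files.
#'
#' @param config a \code{\link{run_config}}.
#' @return list with the per-stage results (\code{coordination},
#'   \code{wave}, \code{network}, \code{architecture}) and the
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_config("config must be a run_config")
  stage <- "inputs"
  res <- list()
  tryCatch({
    if (config$simulate) {
      sim <- do.call(simulation_config,
                     utils::modifyList(list(seed = config$seed), config$sim))
      arch <- generate_architecture(sim)
      gen <- generate_calcium_movie(arch, sim)
      movie <- gen$movie; truth <- gen$truth
    } else {
      if (is.null(config$movie_path)) stop_input("movie_path required")
      movie <- read_movie(config$movie_path)
      arch <- if (!is.null(config$cells_path)) read_cells(config$cells_path)
      truth <- NULL
    }
    stage <- "preprocess"
    sm <- smooth_movie(movie, config$smooth_kernel)
    mask <- mask_islet(sm)
    motion <- assess_motion(sm, cell_width_um = 12)
    if (motion$status == "reject") stop_input("movie rejected for motion")
    if (motion$status == "trim") sm <- trim_movie(sm, motion$t_end)
    dt_movie <- detrend_linear(sm)
    stage <- "coordination"
    blocks <- block_traces(dt_movie, mask)
    cmap <- merge_coordinated(blocks, r_min = config$coordination_r_min)
    cmap$fractions <- list(
      active_fraction = active_fraction(cmap),
      largest_coordinated_fraction = largest_coordinated_fraction(cmap))
    res$coordination <- cmap
    stage <- "wave"
    res$wave <- analyze_wave(blocks, fs = 1 / dt_movie$frame_interval_s,
                             pixel_size_um = dt_movie$pixel_size_um,
                             coordination_fraction =
                               cmap$fractions$largest_coordinated_fraction,
                             mode = config$time_lag_mode)
    stage <- "network"
    if (!is.null(truth)) {
      cts <- extract_cell_traces(dt_movie, truth)
      net <- build_adjacency(cts, R_th = config$network_r_th)
      res$network <- list(network = net,
                          metrics = network_metrics(net, config$hub_cut))
    }
    stage <- "architecture"
    if (!is.null(arch) && nrow(arch$contacts) > 0L)
      res$architecture <- contact_probabilities(arch)
    stage <- "output"
    res$manifest <- .make_manifest(config)
    if (!is.null(config$out_dir)) .write_results(res, config)
    res
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

.make_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # the analysis is identified by its parameters, not
                       # by where its results land
  cfgfile <- tempfile(fileext = ".json")
  on.exit(unlink(cfgfile))
  jsonlite::write_json(cfg, cfgfile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(package = "isletsync",
       version = as.character(utils::packageVersion("isletsync")),
       seed = config$seed,
       config = cfg,
       config_md5 = unname(tools::md5sum(cfgfile)))
}

.write_results <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(
    manifest = res$manifest,
    fractions = res$coordination$fractions,
    n_major_regions = n_major_regions(res$coordination),
    wave = res$wave[c("f_peak_hz", "dt_as_printed_s", "dt_standard_s",
                      "speed_as_printed_um_s", "speed_standard_um_s",
                      "gradient_r2", "eligibility")],
    network = res$network$metrics,
    architecture = if (!is.null(res$architecture))
      as.list(res$architecture$probabilities))
  jsonlite::write_json(summary, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  utils::write.csv(res$coordination$blocks,
                   file.path(config$out_dir, "blocks.csv"), row.names = FALSE)
  utils::write.csv(res$wave$blocks,
                   file.path(config$out_dir, "phase_blocks.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

#' Write a movie as multi-page 16-bit TIFF with a JSON sidecar
#'
#' Pages iterate z fastest, then time; the sidecar records the dimension
#' order (T, Z, Y, X), frame interval, pixel size and saturation value.
#' Intensities are stored on the 16-bit grid scaled by the saturation
#' value (the resolution of typical detectors); data already on that grid
#' round-trips bit-exactly.
#'
#' @param movie an \code{\link{islet_movie}}.
#' @param path output .tif path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "islet_movie"))
  d <- dim(movie$data)
  sat <- if (is.finite(movie$saturation_value)) movie$saturation_value
         else max(movie$data)
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (tt in seq_len(d[1L])) for (z in seq_len(d[2L])) {
    k <- k + 1L
    pages[[k]] <- pmin(pmax(matrix(movie$data[tt, z, , ], d[3L], d[4L]) / sat, 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(dimension_order = "TZYX",
                  n_frames = d[1L], z_planes = d[2L],
                  height = d[3L], width = d[4L],
                  frame_interval_s = movie$frame_interval_s,
                  pixel_size_um = movie$pixel_size_um,
                  saturation_value = sat,
                  z_spacing_um = movie$z_spacing_um)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by \code{\link{write_movie}}
#'
#' @param path .tif path with its .json sidecar alongside.
#' @param axis_order override of the page ordering: "TZYX" (default,
#'   z fastest) or "ZTYX" (t fastest).
#' @return An \code{\link{islet_movie}}.
#' @export
read_movie <- function(path, axis_order = NULL) {
  if (!file.exists(path)) stop_input("movie file not found: ", path)
  scpath <- paste0(path, ".json")
  if (!file.exists(scpath)) stop_input("sidecar not found: ", scpath)
  sc <- jsonlite::fromJSON(scpath)
  order <- axis_order %||% sc$dimension_order
  if (!order %in% c("TZYX", "ZTYX"))
    stop_input("unsupported axis order: ", order)
  pages <- tiff::readTIFF(path, all = TRUE)
  Tn <- sc$n_frames; Z <- sc$z_planes
  if (length(pages) != Tn * Z)
    stop_input("TIFF page count ", length(pages), " does not match sidecar T*Z")
  data <- array(0, dim = c(Tn, Z, sc$height, sc$width))
  k <- 0L
  if (order == "TZYX") {
    for (tt in seq_len(Tn)) for (z in seq_len(Z)) {
      k <- k + 1L; data[tt, z, , ] <- pages[[k]] * sc$saturation_value
    }
  } else {
    for (z in seq_len(Z)) for (tt in seq_len(Tn)) {
      k <- k + 1L; data[tt, z, , ] <- pages[[k]] * sc$saturation_value
    }
  }
  islet_movie(data, frame_interval_s = sc$frame_interval_s,
              pixel_size_um = sc$pixel_size_um,
              saturation_value = sc$saturation_value,
              z_spacing_um = sc$z_spacing_um %||% 8)
}

#' Read a cell table (id, x, y, type) and derive contacts
#'
#' Validates the CSV (missing or invalid types are reported with their
#' row numbers) and derives nearest-neighbor contacts by the generator's
#' rule: pairs within 1.2x the median nearest-neighbor spacing.
#'
#' @param path CSV with columns cell_id (or id), x, y, type.
#' @return An \code{architecture_map}.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop_input("cell table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("id" %in% names(df) && !"cell_id" %in% names(df))
    names(df)[names(df) == "id"] <- "cell_id"
  need <- c("cell_id", "x", "y", "type")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_input("cell table missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$type) | !(df$type %in% c("beta", "alpha", "delta")))
  if (length(bad) > 0L)
    stop_input("missing/invalid cell type at row(s): ",
               paste(bad, collapse = ", "))
  pts <- df[, c("x", "y")]
  d <- as.matrix(stats::dist(pts)); diag(d) <- Inf
  thr <- 1.2 * stats::median(apply(d, 1L, min))
  pair <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
  contacts <- data.frame(i = pair[, 1L], j = pair[, 2L])
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(cells = df[, need], contacts = contacts,
                 spacing_um = stats::median(apply(d, 1L, min)),
                 ellipse = c(a = NA_real_, b = NA_real_)),
            class = "architecture_map")
}

#' Write a coordination label image as 16-bit TIFF
#'
#' One page per z-plane; pixel values are region labels of the block each
#' pixel belongs to (0 = uncoordinated/outside).
#'
#' @param map a \code{coordination_map}.
#' @param dims spatial dims (Z, Y, X) of the analyzed movie.
#' @param path output .tif path.
#' @param block block width used in the analysis (default 5).
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(map, dims, path, block = 5L) {
  stopifnot(inherits(map, "coordination_map"))
  pages <- vector("list", dims[1L])
  for (z in seq_len(dims[1L])) {
    lab <- matrix(0L, dims[2L], dims[3L])
    bl <- map$blocks[map$blocks$z == z & map$blocks$region_label > 0L, ]
    for (r in seq_len(nrow(bl))) {
      yy <- (bl$cy[r] - (block - 1) / 2):(bl$cy[r] + (block - 1) / 2)
      xx <- (bl$cx[r] - (block - 1) / 2):(bl$cx[r] + (block - 1) / 2)
      lab[yy, xx] <- bl$region_label[r]
    }
    pages[[z]] <- lab / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
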