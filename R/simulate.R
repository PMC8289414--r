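#' Simulation configuration for synthetic islets
#'
#' Bundles every knob of the synthetic-data generator: islet composition and
#' cell-type intermixing, acquisition geometry and frame rate, oscillation
#' pattern (slow, fast or mixed), number of phase-independent synchronization
#' domains, optional planar-wave speed, sensor mosaicism, noise, bleaching
#' and saturation. Defaults describe a control-like mouse islet imaged in
#' vivo: ~75% beta cells with low intermixing, a slow oscillation period of
#' a few minutes with fast oscillations riding on the plateau, and a
#' genetically encoded calcium sensor expressed in most beta cells.
#'
#' @param seed integer RNG seed; the whole generator is deterministic given
#'   the seed and the remaining parameters.
#' @param n_cells number of endocrine cells (>= 10).
#' @param type_fractions named numeric of length 3, proportions of
#'   (beta, alpha, delta) cells; must sum to 1.
#' @param intermix degree of cell-type intermixing in [0, 1]: 0 gives the
#'   sorted core--mantle arrangement (beta inward), 1 fully random placement.
#' @param frame_interval_s frame interval in seconds (default 5 s = 0.2 Hz,
#'   one of the standard acquisition rates; the default 120 frames then
#'   span 10 minutes).
#' @param n_frames number of frames.
#' @param z_planes number of z-planes (1, 3, 8 or 12 in typical recordings).
#' @param z_spacing_um spacing between z-planes (default 8 um).
#' @param pixel_size_um lateral pixel size.
#' @param slow_period_s slow oscillation period, seconds; valid range
#'   [60, 620] (observed periods run from about one minute to about ten).
#' @param fast_period_s fast oscillation period, seconds; valid range [4, 31].
#' @param pattern oscillation pattern: "slow", "fast" or "mixed" (fast
#'   oscillations superimposed on the plateau of the slow wave).
#' @param n_domains number K >= 1 of phase-independent synchronization
#'   domains.
#' @param wave_speed_um_s planar-wave propagation speed in um/s, or NULL for
#'   no wave. Requires \code{n_domains = 1}.
#' @param phase_mode "spaced" (default): domain phases are a common
#'   Uniform(0, 2*pi) rotation plus evenly spaced offsets 2*pi*k/K, so each
#'   domain phase is marginally uniform but domains are maximally separated;
#'   "independent": each domain phase drawn independently Uniform(0, 2*pi).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; the oscillation amplitude is 100 units, so SNR = 100/noise_sd).
#' @param bleach_slope_per_s linear photobleaching slope per second, applied
#'   multiplicatively to the mean intensity.
#' @param sensor_fraction fraction of cells expressing the sensor, in (0, 1].
#' @param saturation_value detector saturation ceiling.
#'
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(seed = 1L,
                              n_cells = 100L,
                              type_fractions = c(beta = 0.75, alpha = 0.15, delta = 0.10),
                              intermix = 0.1,
                              frame_interval_s = 5,
                              n_frames = 120L,
                              z_planes = 1L,
                              z_spacing_um = 8,
                              pixel_size_um = 1,
                              slow_period_s = 120,
                              fast_period_s = 15,
                              pattern = c("mixed", "slow", "fast"),
                              n_domains = 1L,
                              wave_speed_um_s = NULL,
                              phase_mode = c("spaced", "independent"),
                              noise_sd = 5,
                              bleach_slope_per_s = 1e-4,
                              sensor_fraction = 0.9,
                              saturation_value = 4095) {
  pattern <- match.arg(pattern)
  phase_mode <- match.arg(phase_mode)
  if (!is.numeric(n_cells) || n_cells < 10)
    stop_config("n_cells must be >= 10")
  if (length(type_fractions) != 3L || any(type_fractions < 0) ||
      abs(sum(type_fractions) - 1) > 1e-9)
    stop_config("type_fractions must be 3 non-negative proportions summing to 1")
  if (intermix < 0 || intermix > 1)
    stop_config("intermix must lie in [0, 1]")
  if (slow_period_s < 60 || slow_period_s > 620)
    stop_config("slow_period_s must lie in [60, 620] s")
  if (fast_period_s < 4 || fast_period_s > 31)
    stop_config("fast_period_s must lie in [4, 31] s")
  if (n_domains < 1)
    stop_config("n_domains must be >= 1")
  if (!is.null(wave_speed_um_s)) {
    if (wave_speed_um_s <= 0)
      stop_config("wave_speed_um_s must be > 0 (or NULL for no wave)")
    if (n_domains != 1L)
      stop_config("a planar wave requires a single synchronization domain")
  }
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (sensor_fraction <= 0 || sensor_fraction > 1)
    stop_config("sensor_fraction must lie in (0, 1]")
  names(type_fractions) <- c("beta", "alpha", "delta")
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 type_fractions = type_fractions, intermix = intermix,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 z_planes = as.integer(z_planes), z_spacing_um = z_spacing_um,
                 pixel_size_um = pixel_size_um,
                 slow_period_s = slow_period_s, fast_period_s = fast_period_s,
                 pattern = pattern, n_domains = as.integer(n_domains),
                 wave_speed_um_s = wave_speed_um_s, phase_mode = phase_mode,
                 noise_sd = noise_sd, bleach_slope_per_s = bleach_slope_per_s,
                 sensor_fraction = sensor_fraction,
                 saturation_value = saturation_value),
            class = "simulation_config")
}

## Geometry constants of the generator: cell spacing (um, ~beta cell
## diameter), islet ellipse aspect ratio, cell footprint radius relative to
## spacing, and depth attenuation length (um) for multi-plane sampling.
.CELL_SPACING_UM <- 12
.ELLIPSE_ASPECT <- 1.4
.FOOTPRINT_FRAC <- 0.58
.DEPTH_LENGTH_UM <- 100
.BASE_BG <- 10
.BASE_CELL <- 20
.AMP <- 100

#' Generate a synthetic islet architecture
#'
#' Places cells on a jittered triangular lattice clipped to an ellipse
#' (islets are compact, roughly ellipsoidal micro-organs), assigns endocrine
#' types by radial sorting (beta cells inward, alpha/delta in the mantle)
#' blended with a random permutation weighted by \code{intermix}, and
#' derives nearest-neighbor contacts as all pairs closer than 1.2x the
#' median nearest-neighbor spacing. With \code{intermix = 0} the contact
#' statistics resemble a sorted control islet; with \code{intermix = 1} a
#' fully intermixed one.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return An object of class \code{architecture_map}: list with
#'   \code{cells} (data.frame: cell_id, x, y, type), \code{contacts}
#'   (data.frame of unordered pairs i < j), \code{spacing_um} and
#'   \code{ellipse} (semi-axes a, b in um).
#' @export
generate_architecture <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_config("config must be a simulation_config")
  with_seed(config$seed, {
    n <- config$n_cells
    s <- .CELL_SPACING_UM
    ## ellipse sized so the hexagonal packing holds ~n cells
    area <- n * sqrt(3) / 2 * s^2
    b <- sqrt(area / (pi * .ELLIPSE_ASPECT))
    a <- .ELLIPSE_ASPECT * b
    pts <- NULL
    repeat {
      xs <- seq(-a - s, a + s, by = s)
      ys <- seq(-b - s, b + s, by = s * sqrt(3) / 2)
      grid <- expand.grid(x = xs, y = ys)
      odd <- (round(grid$y / (s * sqrt(3) / 2)) %% 2) == 1
      grid$x <- grid$x + ifelse(odd, s / 2, 0)
      grid$x <- grid$x + stats::rnorm(nrow(grid), sd = 0.08 * s)
      grid$y <- grid$y + stats::rnorm(nrow(grid), sd = 0.08 * s)
      r2 <- (grid$x / a)^2 + (grid$y / b)^2
      inside <- which(r2 <= 1)
      if (length(inside) >= n) {
        keep <- inside[order(r2[inside])][seq_len(n)]
        pts <- grid[keep, c("x", "y")]
        break
      }
      a <- a * 1.05; b <- b * 1.05
    }
    rownames(pts) <- NULL
    ## radial sorting: beta innermost, alpha/delta mixed in the mantle
    r2 <- (pts$x / a)^2 + (pts$y / b)^2
    nb <- round(config$type_fractions[["beta"]] * n)
    na_ <- round(config$type_fractions[["alpha"]] * n)
    nd <- n - nb - na_
    types <- character(n)
    ord <- order(r2)
    types[ord[seq_len(nb)]] <- "beta"
    mantle <- ord[-seq_len(nb)]
    types[sample(mantle)] <- rep(c("alpha", "delta"), c(na_, nd))
    ## blend with a random permutation of weight `intermix`
    m <- round(config$intermix * n)
    if (m >= 2) {
      idx <- sample.int(n, m)
      types[idx] <- types[idx][sample.int(m)]
    }
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    nn <- apply(d, 1L, min)
    thr <- 1.2 * stats::median(nn)
    pair <- which(d <= thr & upper.tri(d), arr.ind = TRUE)
    contacts <- data.frame(i = pair[, 1L], j = pair[, 2L])
    contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
    rownames(contacts) <- NULL
    structure(list(cells = data.frame(cell_id = seq_len(n),
                                      x = pts$x, y = pts$y,
                                      type = types,
                                      stringsAsFactors = FALSE),
                   contacts = contacts,
                   spacing_um = s,
                   ellipse = c(a = a, b = b)),
              class = "architecture_map")
  })
}

#' @export
print.architecture_map <- function(x, ...) {
  cat(sprintf("architecture_map: %d cells (%s), %d contacts\n",
              nrow(x$cells),
              paste(sprintf("%s %d", names(table(x$cells$type)),
                            as.integer(table(x$cells$type))), collapse = ", "),
              nrow(x$contacts)))
  invisible(x)
}

## Assign cells to K domains as equal-count angular sectors around the
## islet centre, so domain areas are close to equal.
.assign_domains <- function(arch, K) {
  n <- nrow(arch$cells)
  if (K == 1L) return(rep(1L, n))
  ang <- atan2(arch$cells$y, arch$cells$x)
  lab <- integer(n)
  lab[order(ang)] <- rep(seq_len(K), length.out = n,
                         each = ceiling(n / K))[seq_len(n)]
  lab
}

## Rasterize cell positions: label matrix (Y, X) of cell ids, 0 = background.
.rasterize_cells <- function(arch, pixel_size_um) {
  s <- arch$spacing_um
  a <- arch$ellipse[["a"]]; b <- arch$ellipse[["b"]]
  half_x <- a + 1.5 * s
  half_y <- b + 1.5 * s
  nx <- 2L * ceiling(half_x / pixel_size_um)
  ny <- 2L * ceiling(half_y / pixel_size_um)
  px <- (seq_len(nx) - 0.5 - nx / 2) * pixel_size_um
  py <- (seq_len(ny) - 0.5 - ny / 2) * pixel_size_um
  lab <- matrix(0L, ny, nx)
  r <- .FOOTPRINT_FRAC * s
  ## nearest cell within footprint radius wins each pixel
  P <- as.matrix(expand.grid(y = py, x = px))
  C <- as.matrix(arch$cells[, c("y", "x")])
  best_d2 <- rep(r^2, nrow(P))
  best_id <- integer(nrow(P))
  for (i in seq_len(nrow(C))) {
    d2 <- (P[, 1L] - C[i, 1L])^2 + (P[, 2L] - C[i, 2L])^2
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_id[hit] <- i
  }
  lab[] <- best_id
  attr(lab, "pixel_x_um") <- px
  attr(lab, "pixel_y_um") <- py
  lab
}

## Clean (noiseless, unit-amplitude) per-cell oscillation in [0, 1].
## The slow component is a smoothed square (relaxation-type) wave whose
## plateau occupies `duty` (default 0.5) of the cycle.
.clean_oscillation <- function(t, pattern, P_slow, P_fast, phase, delay,
                               duty = 0.5) {
  ts <- t - delay
  cthr <- sin(pi * (0.5 - duty))
  slow <- stats::plogis((sin(2 * pi * ts / P_slow + phase) - cthr) / 0.15)
  if (pattern == "slow") return(slow)
  fast <- 0.5 + 0.5 * sin(2 * pi * ts / P_fast + phase)
  if (pattern == "fast") return(fast)
  ## mixed: fast oscillation gated to the plateau of the slow wave
  0.7 * slow + 0.3 * slow * fast
}

#' Generate a synthetic calcium movie with ground truth
#'
#' Emits a 4-D fluorescence movie over the given architecture, together
#' with per-cell ground truth for parameter-recovery testing. Each of K
#' synchronization domains oscillates at the configured period with its own
#' phase; within a planar-wave domain the per-cell phase delay grows
#' linearly with projected distance along the wave axis (the ellipse major
#' axis) at the configured speed. A sensor mosaic silences a fraction of
#' cells; Gaussian noise, linear multiplicative bleaching, depth-attenuated
#' z-planes and saturation clipping complete the acquisition model.
#'
#' @param arch an \code{architecture_map}.
#' @param config a \code{simulation_config}.
#' @return list with elements \code{movie} (\code{\link{islet_movie}}) and
#'   \code{truth} (class \code{ground_truth}): \code{domain_label},
#'   \code{phase_offset}, \code{delay_s}, \code{true_wave_speed_um_s},
#'   \code{active_cells}, \code{clean_traces} (cells x T, intensity units at
#'   the first z-plane, noiseless and bleach-free), and \code{cell_pixels}
#'   (Y x X label matrix of cell ids).
#' @export
generate_calcium_movie <- function(arch, config) {
  if (!inherits(arch, "architecture_map")) stop_config("arch must be an architecture_map")
  if (!inherits(config, "simulation_config")) stop_config("config must be a simulation_config")
  with_seed(config$seed, {
    n <- nrow(arch$cells)
    K <- config$n_domains
    Tn <- config$n_frames
    dt <- config$frame_interval_s
    t <- (seq_len(Tn) - 1) * dt
    dom <- .assign_domains(arch, K)
    if (config$phase_mode == "spaced") {
      rot <- stats::runif(1, 0, 2 * pi)
      dphase <- (rot + 2 * pi * (seq_len(K) - 1) / K) %% (2 * pi)
    } else {
      dphase <- stats::runif(K, 0, 2 * pi)
    }
    phase <- dphase[dom]
    delay <- rep(0, n)
    if (!is.null(config$wave_speed_um_s)) {
      delay <- (arch$cells$x - min(arch$cells$x)) / config$wave_speed_um_s
    }
    ## cells within 1.8x the lattice spacing of another domain are silent
    ## (baseline fluorescence, no oscillation): synchronization domains in
    ## functionally disrupted islets are separated by weakly active cells,
    ## and this keeps domain interfaces optically unmixed
    oscillating <- rep(TRUE, n)
    n_drop <- round((1 - config$sensor_fraction) * n)
    expressing <- rep(TRUE, n)
    if (n_drop > 0) expressing[sample.int(n, n_drop)] <- FALSE
    if (K > 1L) {
      d <- as.matrix(stats::dist(arch$cells[, c("x", "y")]))
      othr <- outer(dom, dom, "!=")
      near_border <- apply(d < 1.8 * arch$spacing_um & othr, 1L, any)
      oscillating[near_border] <- FALSE
      ## equalize active-cell counts across domains (the domains are equal
      ## by contract): excess cells nearest a domain border join the
      ## silent band
      counts <- tapply(expressing & oscillating, dom, sum)
      target <- min(counts)
      for (k in seq_len(K)) {
        excess <- counts[[k]] - target
        if (excess > 0) {
          cand <- which(dom == k & expressing & oscillating)
          border_d <- apply(d[cand, dom != k, drop = FALSE], 1L, min)
          oscillating[cand[order(border_d)][seq_len(excess)]] <- FALSE
        }
      }
    }
    active <- expressing & oscillating
    clean <- matrix(0, n, Tn)
    for (i in seq_len(n)) {
      clean[i, ] <- if (oscillating[i])
        .clean_oscillation(t, config$pattern, config$slow_period_s,
                           config$fast_period_s, phase[i], delay[i])
      else rep(0, Tn)
    }
    ## intensity traces at z-plane 1 (no attenuation)
    intens <- .BASE_CELL + .AMP * clean
    lab <- .rasterize_cells(arch, config$pixel_size_um)
    ny <- nrow(lab); nx <- ncol(lab)
    Z <- config$z_planes
    atten <- exp(-(seq_len(Z) - 1) * config$z_spacing_um / .DEPTH_LENGTH_UM)
    data <- array(0, dim = c(Tn, Z, ny, nx))
    live <- which(expressing)
    for (z in seq_len(Z)) {
      ## column 1 = background; signal above background attenuated with depth
      tr <- matrix(.BASE_BG, Tn, n + 1L)
      tr[, live + 1L] <- .BASE_BG +
        t((intens[live, , drop = FALSE] - .BASE_BG) * atten[z])
      data[, z, , ] <- tr[, as.vector(lab) + 1L]
    }
    ## linear bleaching applied multiplicatively to the mean
    if (config$bleach_slope_per_s != 0) {
      fac <- pmax(0, 1 - config$bleach_slope_per_s * t)
      data <- data * fac  # recycles over the first (time) axis
    }
    if (config$noise_sd > 0) {
      data <- data + stats::rnorm(length(data), sd = config$noise_sd)
    }
    data <- pmin(pmax(data, 0), config$saturation_value)
    movie <- islet_movie(data, frame_interval_s = dt,
                         pixel_size_um = config$pixel_size_um,
                         saturation_value = config$saturation_value,
                         z_spacing_um = config$z_spacing_um)
    truth <- structure(list(domain_label = dom,
                            phase_offset = phase,
                            delay_s = delay,
                            true_wave_speed_um_s = config$wave_speed_um_s,
                            active_cells = active,
                            clean_traces = intens,
                            cell_pixels = lab,
                            config = config),
                       class = "ground_truth")
    list(movie = movie, truth = truth)
  })
}

#' Generate a synthetic perfusion movie with vessel mask and ground truth
#'
#' Models the arrival of a fluorescent glucose analog injected into the
#' circulation: vessel pixels rise first with a logistic bolus; tissue
#' pixels rise after a delay that grows with distance from the nearest
#' vessel, with diffusion-like spatial smoothing of the delay field.
#' Recorded at 1 Hz in a single plane, matching the acquisition used for
#' perfusion imaging.
#'
#' @param arch an \code{architecture_map} (sets the field of view).
#' @param config a \code{simulation_config} (seed, pixel size, n_frames,
#'   noise_sd, saturation).
#' @param tissue_delay_s_per_um arrival delay per micrometre of distance
#'   from the nearest vessel (0 gives instantaneous, uniform perfusion).
#' @param bolus_time_s time of the bolus arrival in the vessel, seconds.
#' @param rise_tau_s logistic rise time constant, seconds.
#' @param vessel_halfwidth_um half-width of the vessel footprint.
#' @param smooth_sigma_um Gaussian smoothing of the delay field.
#' @return list with \code{movie} (\code{islet_movie}, single z-plane),
#'   \code{vessel_mask} (logical Y x X), and \code{truth} (list with
#'   per-pixel \code{arrival_delay_s} and the bolus parameters).
#' @export
generate_perfusion_movie <- function(arch, config,
                                     tissue_delay_s_per_um = 0.15,
                                     bolus_time_s = 20,
                                     rise_tau_s = 1.5,
                                     vessel_halfwidth_um = 4,
                                     smooth_sigma_um = 3) {
  if (!inherits(arch, "architecture_map")) stop_config("arch must be an architecture_map")
  if (!inherits(config, "simulation_config")) stop_config("config must be a simulation_config")
  if (tissue_delay_s_per_um < 0) stop_config("tissue_delay_s_per_um must be >= 0")
  with_seed(config$seed, {
    px <- config$pixel_size_um
    lab <- .rasterize_cells(arch, px)
    ny <- nrow(lab); nx <- ncol(lab)
    xs <- attr(lab, "pixel_x_um"); ys <- attr(lab, "pixel_y_um")
    a <- arch$ellipse[["a"]]; b <- arch$ellipse[["b"]]
    ## auto-placed vessel: gentle sinusoid along the major axis
    X <- matrix(xs, ny, nx, byrow = TRUE)
    Y <- matrix(ys, ny, nx)
    vy <- 0.3 * b * sin(pi * X / a)
    vessel <- abs(Y - vy) <= vessel_halfwidth_um
    dist_um <- .distance_to_mask(vessel) * px
    delay <- dist_um * tissue_delay_s_per_um
    if (smooth_sigma_um > 0 && tissue_delay_s_per_um > 0) {
      delay <- EBImage::gblur(delay, sigma = smooth_sigma_um / px)
      delay[vessel] <- 0
      delay <- pmax(delay, 0)
    }
    Tn <- config$n_frames
    t <- seq_len(Tn) - 1  # 1 Hz
    data <- array(0, dim = c(Tn, 1L, ny, nx))
    dv <- as.vector(delay)
    ## logistic bolus, delayed per pixel
    tm <- outer(t, dv, function(tt, d) stats::plogis((tt - bolus_time_s - d) / rise_tau_s))
    data[, 1L, , ] <- .BASE_BG + .AMP * tm
    if (config$noise_sd > 0)
      data <- data + stats::rnorm(length(data), sd = config$noise_sd)
    data <- pmin(pmax(data, 0), config$saturation_value)
    movie <- islet_movie(data, frame_interval_s = 1, pixel_size_um = px,
                         saturation_value = config$saturation_value)
    list(movie = movie,
         vessel_mask = vessel,
         truth = list(arrival_delay_s = delay,
                      bolus_time_s = bolus_time_s,
                      rise_tau_s = rise_tau_s,
                      tissue_delay_s_per_um = tissue_delay_s_per_um))
  })
}

## Euclidean distance (pixels) from every pixel to the nearest TRUE pixel.
.distance_to_mask <- function(mask) {
  if (!any(mask)) stop_input("mask has no foreground pixels")
  d <- EBImage::distmap(EBImage::Image(1 - mask))
  m <- matrix(as.numeric(EBImage::imageData(d)), nrow(mask), ncol(mask))
  m
}
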