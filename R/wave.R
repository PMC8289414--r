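## Oscillation frequency, per-block phase at the peak frequency, phase lag
## between the maximum- and minimum-phase regions, and wave propagation
## speed across the islet.

#' Peak frequency of the islet-average time course
#'
#' The raw periodogram of the (detrended, mean-subtracted) trace; the peak
#' frequency is the argmax over (0, fs/2], DC excluded, nearest-bin (no
#' interpolation).
#'
#' @param trace islet-average time course (length >= 32).
#' @param fs sampling frequency, Hz.
#' @return list with \code{f_peak_hz}, \code{frequency} and \code{power}
#'   (one-sided, DC excluded).
#' @export
power_spectrum_peak <- function(trace, fs) {
  Tn <- length(trace)
  if (Tn < 32L) stop_input("spectrum needs at least 32 samples")
  if (max(trace) == min(trace)) stop_undefined("constant trace has no spectral peak")
  x <- trace - mean(trace)
  P <- Mod(stats::fft(x))^2
  k <- seq_len(floor(Tn / 2))
  f <- k * fs / Tn
  list(f_peak_hz = f[which.max(P[k + 1L])], frequency = f, power = P[k + 1L])
}

#' Phase of a time course at a given frequency
#'
#' Argument of the discrete Fourier component at the bin nearest
#' \code{f_peak}. Result lies in (-pi, pi]; a delay of tau seconds shifts
#' the phase by -2*pi*f_peak*tau.
#'
#' @param trace block time course.
#' @param f_peak frequency (Hz) at which to evaluate the phase.
#' @param fs sampling frequency, Hz.
#' @return phase in radians.
#' @export
phase_at_peak <- function(trace, f_peak, fs) {
  Tn <- length(trace)
  k <- round(f_peak * Tn / fs)
  if (k < 1L || k > floor(Tn / 2)) stop_input("f_peak outside (0, fs/2]")
  Arg(stats::fft(trace - mean(trace))[k + 1L])
}

#' Convert a phase difference into a time lag
#'
#' Two conversions are provided. \code{"as_printed"} evaluates the formula
#' used in the original wave analysis literally,
#' \code{dt = (1/f) * atan(phi1 - phi2)} with \code{f} the sampling
#' frequency, and is the default for fidelity of reproduction.
#' \code{"standard"} is the dimensionally conventional conversion
#' \code{dt = (phi1 - phi2) / (2*pi*f)} with \code{f} the oscillation's
#' peak frequency, and is the mode used for parameter recovery. Both are
#' antisymmetric in the two phases.
#'
#' @param phi1 phase of the maximum-phase region (radians).
#' @param phi2 phase of the minimum-phase region (radians).
#' @param f frequency in Hz: the sampling frequency for
#'   \code{"as_printed"}, the oscillation peak frequency for
#'   \code{"standard"}.
#' @param mode "as_printed" or "standard".
#' @return time lag dt in seconds.
#' @export
time_lag <- function(phi1, phi2, f, mode = c("as_printed", "standard")) {
  mode <- match.arg(mode)
  if (f <= 0) stop_input("f must be > 0")
  switch(mode,
         as_printed = (1 / f) * atan(phi1 - phi2),
         standard = (phi1 - phi2) / (2 * pi * f))
}

#' Phase map and wave metrics of a coordinated islet
#'
#' Computes the islet-average peak frequency, per-block phases at that
#' frequency (only blocks correlating > 0.7 with the islet average are
#' included), the maximum phase lag converted to a time lag in both modes,
#' the wave speed (centroid distance between the maximum- and
#' minimum-phase blocks divided by the time lag), and the eligibility
#' status. Phases are rotated so their circular mean is zero before
#' comparison, avoiding wrap-around at +/- pi.
#'
#' @param blocks a \code{block_trace_set} (see \code{\link{block_traces}}).
#' @param fs sampling frequency, Hz.
#' @param pixel_size_um pixel size (for centroid distances).
#' @param coordination_fraction the islet's largest coordinated fraction,
#'   used by the eligibility gate (> 0.80 required).
#' @param include_r correlation with the islet average required for a
#'   block to enter the phase map (default 0.7).
#' @param mode default time-lag mode (see \code{\link{time_lag}}).
#' @return An object of class \code{phase_map}: list with
#'   \code{f_peak_hz}, \code{blocks} (block_id, z, cy_um, cx_um, phi,
#'   included), \code{dt_as_printed_s}, \code{dt_standard_s},
#'   \code{speed_as_printed_um_s}, \code{speed_standard_um_s},
#'   \code{gradient_r2}, \code{eligibility} ("eligible",
#'   "low_coordination" or "no_phase_transition") and \code{mode}.
#' @export
analyze_wave <- function(blocks, fs, pixel_size_um, coordination_fraction,
                         include_r = 0.7, mode = c("as_printed", "standard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(blocks, "block_trace_set"))
  info <- blocks$info
  avg <- rowMeans(blocks$traces)
  ps <- power_spectrum_peak(avg, fs)
  f_peak <- ps$f_peak_hz
  rr <- suppressWarnings(as.vector(stats::cor(blocks$traces, avg)))
  rr[is.na(rr)] <- 0
  included <- rr > include_r
  phi <- rep(NA_real_, nrow(info))
  phi[included] <- vapply(which(included), function(b)
    phase_at_peak(blocks$traces[, b], f_peak, fs), numeric(1))
  ## rotate phases so the circular mean is zero (unwrap about the bulk)
  if (any(included)) {
    mu <- Arg(sum(exp(1i * phi[included])))
    phi[included] <- Arg(exp(1i * (phi[included] - mu)))
  }
  out <- list(f_peak_hz = f_peak,
              blocks = data.frame(block_id = info$block_id, z = info$z,
                                  cy_um = info$cy * pixel_size_um,
                                  cx_um = info$cx * pixel_size_um,
                                  phi = phi, included = included),
              mode = mode)
  if (sum(included) >= 3L) {
    i1 <- which.max(phi)  # NA-safe: NAs never win which.max
    i2 <- which.min(phi)
    dphi <- phi[i1] - phi[i2]
    out$dt_as_printed_s <- time_lag(phi[i1], phi[i2], fs, "as_printed")
    out$dt_standard_s <- time_lag(phi[i1], phi[i2], f_peak, "standard")
    dist_um <- sqrt((info$cy[i1] - info$cy[i2])^2 +
                    (info$cx[i1] - info$cx[i2])^2) * pixel_size_um
    out$extreme_blocks <- c(max_phase = info$block_id[i1],
                            min_phase = info$block_id[i2])
    out$distance_um <- dist_um
    out$speed_as_printed_um_s <-
      if (out$dt_as_printed_s > 0) dist_um / out$dt_as_printed_s else Inf
    out$speed_standard_um_s <-
      if (out$dt_standard_s > 0) dist_um / out$dt_standard_s else Inf
    ## "clear phase transition": linear fit of phase against position
    fit <- stats::lm(phi ~ cy_um + cx_um,
                     data = out$blocks[out$blocks$included, ])
    out$gradient_r2 <- summary(fit)$r.squared
  } else {
    out$gradient_r2 <- NA_real_
  }
  out$eligibility <- eligibility_gate(coordination_fraction, out)
  class(out) <- "phase_map"
  out
}

#' Eligibility of an islet for wave speed analysis
#'
#' Speed and phase lag are reported only for islets with more than 80%
#' coordinated area and a clear phase transition across the islet,
#' operationalized as R^2 >= 0.5 for the linear fit of block phase against
#' position.
#'
#' @param coordination_fraction largest coordinated fraction in [0, 1].
#' @param phase_map a \code{phase_map} (or a list with
#'   \code{gradient_r2}).
#' @param min_fraction coordination gate (default 0.80, strict).
#' @param min_r2 gradient-fit gate (default 0.5).
#' @return "eligible", "low_coordination" or "no_phase_transition".
#' @export
eligibility_gate <- function(coordination_fraction, phase_map,
                             min_fraction = 0.80, min_r2 = 0.5) {
  if (!(coordination_fraction > min_fraction)) return("low_coordination")
  r2 <- phase_map$gradient_r2
  if (is.null(r2) || is.na(r2) || r2 < min_r2) return("no_phase_transition")
  "eligible"
}

#' Wave propagation speed from a phase map
#'
#' Distance between the maximum- and minimum-phase block centroids divided
#' by the time lag, in the requested mode. Reported only for eligible
#' islets; a zero time lag flags infinite speed and is excluded.
#'
#' @param phase_map a \code{phase_map} from \code{\link{analyze_wave}}.
#' @param mode time-lag mode (defaults to the map's mode).
#' @return speed in um/s, or NA with a message when the islet is not
#'   eligible.
#' @export
wave_speed <- function(phase_map, mode = phase_map$mode) {
  stopifnot(inherits(phase_map, "phase_map"))
  if (phase_map$eligibility != "eligible") {
    message("islet not eligible for wave speed (", phase_map$eligibility, ")")
    return(NA_real_)
  }
  sp <- switch(mode, as_printed = phase_map$speed_as_printed_um_s,
               standard = phase_map$speed_standard_um_s)
  if (!is.finite(sp)) {
    message("zero time lag: infinite speed flagged, excluded")
    return(NA_real_)
  }
  sp
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase_map: f_peak %.4g Hz, %d/%d blocks included, %s\n",
              x$f_peak_hz, sum(x$blocks$included), nrow(x$blocks),
              x$eligibility))
  if (!is.null(x$dt_standard_s))
    cat(sprintf("  dt %.3g s (as printed) / %.3g s (standard); speed %.3g / %.3g um/s\n",
                x$dt_as_printed_s, x$dt_standard_s,
                x$speed_as_printed_um_s, x$speed_standard_um_s))
  invisible(x)
}
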