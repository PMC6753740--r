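#' Breathing trace object
#'
#' A uniformly sampled surrogate-marker position trace. Positions are in
#' cm; after [preprocess_trace()] the quiescent minimum sits at the
#' common baseline y = 0.
#'
#' @param time Sample times, s (uniform).
#' @param position Surrogate positions, cm.
#' @param rate Sampling rate, Hz.
#' @param meta Preprocessing metadata list.
#' @return An object of class `breathing_trace`.
#' @export
breathing_trace <- function(time, position, rate, meta = list()) {
  if (length(time) < 2L || length(time) != length(position))
    stop_domain("trace needs >= 2 matched (time, position) samples")
  if (any(!is.finite(time)) || any(!is.finite(position)))
    stop_domain("trace samples must be finite")
  dt <- diff(time)
  if (any(dt <= 0)) stop_domain("trace time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop_domain("trace must be uniformly sampled")
  structure(list(time = time, position = position, rate = rate,
                 meta = meta),
            class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  cat(sprintf(
    "<breathing_trace> %.1f s at %g Hz; range [%.3f, %.3f] cm%s\n",
    trace_duration(x), x$rate, min(x$position), max(x$position),
    if (isTRUE(x$meta$smoothed)) " (preprocessed)" else ""))
  invisible(x)
}

#' Trace duration in seconds
#' @param trace A `breathing_trace`.
#' @export
trace_duration <- function(trace) {
  trace$time[length(trace$time)] - trace$time[1]
}

#' Load a breathing trace from a two-column text file
#'
#' Expects whitespace- or comma-delimited columns (time s, position cm);
#' lines starting with `#` are comments. Non-uniform input is resampled
#' to `rate` by linear interpolation; input already at `rate` is kept
#' sample-exact.
#'
#' @param path File path.
#' @param rate Target sampling rate, Hz (default 40).
#' @return A `breathing_trace`.
#' @export
load_trace <- function(path, rate = 40) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_domain("trace file has fewer than 2 samples")
  dat <- read.table(text = gsub(",", " ", lines))
  if (ncol(dat) < 2L) stop_domain("trace file must have two columns")
  t <- as.numeric(dat[[1]]); y <- as.numeric(dat[[2]])
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop_domain("trace file contains non-numeric or NaN samples")
  if (any(diff(t) <= 0))
    stop_domain("trace time must be strictly increasing")
  dt <- diff(t)
  if (max(dt) - min(dt) <= 1e-9 && abs(mean(dt) - 1 / rate) <= 1e-9) {
    return(breathing_trace(t, y, rate))
  }
  tt <- seq(t[1], t[length(t)], by = 1 / rate)
  yy <- approx(t, y, xout = tt)$y
  breathing_trace(tt, yy, rate, meta = list(resampled = TRUE))
}

#' Write a trace in the two-column text format
#' @param trace A `breathing_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_s position_cm", con)
  writeLines(sprintf("%.6f %.8f", trace$time, trace$position), con)
  invisible(path)
}

#' Standardize a breathing trace
#'
#' Applies the three preprocessing steps used to put surrogate traces on
#' a common footing: (1) Savitzky-Golay smoothing (polynomial order 2,
#' moving span of 1 s); (2) a multiplicative scale factor so the RMS
#' amplitude about the trace mean equals `target_rms` — the default,
#' \eqn{1/(2\sqrt{2})} cm, is the RMS of a sinusoid of 1-cm peak-to-peak
#' amplitude; (3) an additive shift placing the quiescent minimum
#' (a low quantile of the samples, robust to single-sample dips) at
#' y = 0.
#'
#' @param trace A `breathing_trace` of duration >= 2 s.
#' @param target_rms Target RMS amplitude about the mean, cm.
#' @param quiescent_quantile Quantile defining the quiescent minimum
#'   (default 0.05).
#' @param span Smoothing span, s (default 1).
#' @param order Savitzky-Golay polynomial order (default 2).
#' @return The standardized `breathing_trace`; `meta` records the filter,
#'   scale factor, and baseline offset applied.
#' @export
preprocess_trace <- function(trace, target_rms = 1 / (2 * sqrt(2)),
                             quiescent_quantile = 0.05,
                             span = 1, order = 2) {
  stopifnot(inherits(trace, "breathing_trace"))
  if (trace_duration(trace) < 2)
    stop_domain("trace must be at least 2 s long")
  n <- round(span * trace$rate)
  if (n %% 2 == 0) n <- n + 1
  n <- max(n, order + 2 + (order %% 2))  # odd, > order
  y <- signal::sgolayfilt(trace$position, p = order, n = n)
  rms <- sqrt(mean((y - mean(y))^2))
  if (rms < 1e-12)
    stop_domain("zero-variance trace cannot be RMS-scaled")
  scale <- target_rms / rms
  y <- y * scale
  offset <- quantile(y, quiescent_quantile, names = FALSE)
  y <- y - offset
  breathing_trace(trace$time, y, trace$rate,
                  meta = list(smoothed = TRUE, sg_order = order,
                              sg_window = n, scale_factor = scale,
                              baseline_offset = offset,
                              target_rms = target_rms))
}

#' Synthesize a breathing trace
#'
#' Two generators: `"sin4"` is the idealized model
#' \eqn{y(t) = A \sin^4(\pi t / T)}; `"irregular"` emulates real
#' surrogate traces by drawing per-cycle amplitude and period from
#' mean-preserving lognormal distributions and letting the baseline
#' follow a random walk (linearly interpolated across each cycle so the
#' trace stays continuous).
#'
#' @param kind `"irregular"` or `"sin4"`.
#' @param peak_to_peak Nominal amplitude A, cm (default 1).
#' @param period Nominal breathing period T, s (default 5).
#' @param amplitude_cv,period_cv Coefficients of variation of the
#'   per-cycle amplitude and period (irregular only).
#' @param baseline_sd Baseline random-walk step per cycle, cm.
#' @param duration Trace length, s (default 120).
#' @param rate Sampling rate, Hz (default 40).
#' @param seed Optional seed; identical seeds give byte-identical traces.
#' @return A `breathing_trace`.
#' @export
synth_trace <- function(kind = c("irregular", "sin4"), peak_to_peak = 1,
                        period = 5, amplitude_cv = 0.15, period_cv = 0.15,
                        baseline_sd = 0.05, duration = 120, rate = 40,
                        seed = NULL) {
  kind <- match.arg(kind)
  check_scalar(peak_to_peak, "peak_to_peak")
  check_scalar(period, "period")
  check_scalar(duration, "duration")
  if (amplitude_cv < 0 || period_cv < 0 || baseline_sd < 0)
    stop_domain("jitter parameters must be >= 0")
  tt <- seq(0, duration, by = 1 / rate)
  if (kind == "sin4") {
    y <- peak_to_peak * sin(pi * tt / period)^4
    return(breathing_trace(tt, y, rate, meta = list(kind = "sin4")))
  }
  with_seed(seed, {
    ncyc <- ceiling(duration / period * (1 + 5 * period_cv)) + 3L
    lsd_t <- sqrt(log1p(period_cv^2))
    lsd_a <- sqrt(log1p(amplitude_cv^2))
    periods <- period * exp(rnorm(ncyc, -lsd_t^2 / 2, lsd_t))
    amps <- peak_to_peak * exp(rnorm(ncyc, -lsd_a^2 / 2, lsd_a))
    bases <- cumsum(c(0, rnorm(ncyc, 0, baseline_sd)))
    starts <- cumsum(c(0, periods))
    while (starts[length(starts) - 1] < duration) {
      periods <- c(periods, period * exp(rnorm(1, -lsd_t^2 / 2, lsd_t)))
      amps <- c(amps, peak_to_peak * exp(rnorm(1, -lsd_a^2 / 2, lsd_a)))
      bases <- c(bases, bases[length(bases)] + rnorm(1, 0, baseline_sd))
      starts <- c(starts, starts[length(starts)] + periods[length(periods)])
    }
    ci <- findInterval(tt, starts, rightmost.closed = FALSE)
    ci[ci < 1] <- 1L
    phase <- (tt - starts[ci]) / periods[ci]
    base <- bases[ci] + (bases[ci + 1L] - bases[ci]) * phase
    y <- base + amps[ci] * sin(pi * phase)^4
    breathing_trace(tt, y, rate,
                    meta = list(kind = "irregular", seed = seed))
  })
}

#' Motion model: 1D surrogate mapped to a 3D displacement axis
#'
#' The trace drives displacement along one lateral axis in the plane
#' orthogonal to the beam: `"parallel"` moves the target along the fast
#' raster scan axis (x), `"orthogonal"` along the step axis (y). The
#' other components are zero.
#'
#' @param trace A `breathing_trace`.
#' @param axis `"parallel"` or `"orthogonal"`.
#' @param amplitude_scale Dimensionless scale applied to the trace when
#'   mapping to target displacement.
#' @param extend Behavior past the recorded duration: `"tile"` repeats
#'   the trace periodically (deliveries can outlast a recording);
#'   `"error"` raises instead.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(trace, axis = c("parallel", "orthogonal"),
                         amplitude_scale = 1, extend = c("tile", "error")) {
  stopifnot(inherits(trace, "breathing_trace"))
  axis <- match.arg(axis)
  extend <- match.arg(extend)
  structure(list(trace = trace, axis = axis,
                 amplitude_scale = amplitude_scale, extend = extend),
            class = "motion_model")
}

# Surrogate position (cm) at arbitrary times, with tiling past the
# recorded duration.
trace_value <- function(trace, t, extend = "tile") {
  dur <- trace_duration(trace)
  t0 <- trace$time[1]
  tt <- t - t0
  if (extend == "error" && any(tt < -1e-9 | tt > dur + 1e-9))
    stop_domain("time outside the recorded trace")
  tt <- tt %% dur
  approx(trace$time - t0, trace$position, xout = tt, rule = 2)$y
}

#' Target displacement at time t
#'
#' @param model A [motion_model()].
#' @param t Time(s), s.
#' @return An n x 3 matrix of displacements (dx, dy, dz) in mm.
#' @export
displacement_at <- function(model, t) {
  stopifnot(inherits(model, "motion_model"))
  y <- trace_value(model$trace, t, model$extend) * model$amplitude_scale
  d <- matrix(0, length(t), 3L,
              dimnames = list(NULL, c("dx_mm", "dy_mm", "dz_mm")))
  if (model$axis == "parallel") d[, 1] <- y * 10 else d[, 2] <- y * 10
  d
}
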