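#' Machine timing parameters
#'
#' Synchrotron and scanning timing constants of the delivery system,
#' plus the charge-per-MU conversion. Defaults describe a clinical
#' synchrotron-based spot scanning system.
#'
#' @param energy_switch_time Energy switching / charge refill time, s.
#' @param charge_capacity Synchrotron charge capacity, nC.
#' @param charge_hold_time Flat-top charge hold time, s: a timer starting
#'   at refill completion; on expiry residual charge is dumped and a
#'   refill is required before the next spill.
#' @param spill_rate Charge spill (extraction) rate, nC/s.
#' @param scan_rate Beam scan rate along the fast raster axis, m/s.
#' @param step_rate Orthogonal step rate, m/s.
#' @param spot_verification_time Spot position verification time, s,
#'   charged once per delivery event (every repaint pass included).
#' @param gate_off_buffer Latency between gate-off and beam-off, s: the
#'   beam still delivers for this long after the surrogate leaves the
#'   gate.
#' @param gate_on_buffer Latency between gate-on and beam-on, s.
#' @param charge_per_mu Charge extracted per MU, nC/MU. Not a published
#'   machine constant; the default puts a clinical-scale (~1e2 MU) plan
#'   in the regime of tens of refills.
#' @param min_mu Minimum deliverable MU.
#' @return An object of class `machine_timing`.
#' @export
machine_timing <- function(energy_switch_time = 2.3,
                           charge_capacity = 2,
                           charge_hold_time = 8,
                           spill_rate = 0.5,
                           scan_rate = 10,
                           step_rate = 6,
                           spot_verification_time = 0.0025,
                           gate_off_buffer = 0.040,
                           gate_on_buffer = 0.200,
                           charge_per_mu = 0.1,
                           min_mu = 0.001) {
  vals <- list(energy_switch_time = energy_switch_time,
               charge_capacity = charge_capacity,
               charge_hold_time = charge_hold_time,
               spill_rate = spill_rate, scan_rate = scan_rate,
               step_rate = step_rate,
               spot_verification_time = spot_verification_time,
               gate_off_buffer = gate_off_buffer,
               gate_on_buffer = gate_on_buffer,
               charge_per_mu = charge_per_mu, min_mu = min_mu)
  for (nm in names(vals)) check_scalar(vals[[nm]], nm)
  structure(vals, class = "machine_timing")
}

#' @export
print.machine_timing <- function(x, ...) {
  cat("<machine_timing>\n")
  cat(sprintf("  energy switch/refill %.3g s, capacity %.3g nC, hold %.3g s, spill %.3g nC/s\n",
              x$energy_switch_time, x$charge_capacity, x$charge_hold_time,
              x$spill_rate))
  cat(sprintf("  scan %.3g m/s, step %.3g m/s, verification %.3g ms\n",
              x$scan_rate, x$step_rate, 1e3 * x$spot_verification_time))
  cat(sprintf("  gate buffers off/on %.0f/%.0f ms, %.3g nC/MU, min %.3g MU\n",
              1e3 * x$gate_off_buffer, 1e3 * x$gate_on_buffer,
              x$charge_per_mu, x$min_mu))
  invisible(x)
}

#' Gating / repainting configuration
#'
#' Amplitude gating enables the beam while the surrogate position is
#' below `threshold` (cm); maximum-MU layered repainting caps every
#' individual spot delivery at `max_mu`. `NULL` disables the technique.
#'
#' @param threshold Gate level, cm, or `NULL` for no gating.
#' @param max_mu Maximum MU per delivery, or `NULL` for no repainting.
#' @return `gate_config` / `repaint_config` objects.
#' @export
gate_config <- function(threshold = NULL) {
  if (!is.null(threshold)) check_scalar(threshold, "threshold")
  structure(list(threshold = threshold), class = "gate_config")
}

#' @rdname gate_config
#' @export
repaint_config <- function(max_mu = NULL) {
  if (!is.null(max_mu)) check_scalar(max_mu, "max_mu")
  structure(list(max_mu = max_mu), class = "repaint_config")
}

#' Partition a spot weight into repaint passes
#'
#' Implements maximum-MU layered repainting: each pass delivers at most
#' `max_mu`; the only exception occurs when the remainder after a pass
#' would fall below the minimum deliverable MU, in which case the
#' preceding pass absorbs it (exceeding `max_mu` by less than `min_mu`).
#' Parts are constructed by cumulative subtraction so that their
#' left-to-right floating-point sum reproduces `weight` exactly.
#'
#' @param weight Planned spot weight, MU (>= `min_mu`).
#' @param max_mu Cap per delivery; `NULL`/`Inf` means no repainting.
#' @param min_mu Minimum deliverable MU.
#' @return Numeric vector of per-pass MU.
#' @export
repaint_partition <- function(weight, max_mu = Inf, min_mu = 0.001) {
  tol <- 1e-9
  if (is.null(max_mu)) max_mu <- Inf
  if (!is.finite(weight) || weight < min_mu - tol)
    stop_domain("weight below the minimum deliverable MU")
  if (is.finite(max_mu) && max_mu < min_mu - tol)
    stop_domain("max_mu must be >= min_mu")
  if (weight <= max_mu + tol) return(weight)
  q <- floor(weight / max_mu + tol)
  rem <- weight - q * max_mu
  n <- if (rem > tol && rem < min_mu - tol) q       # absorb into last pass
       else q + (rem > tol)
  parts <- rep(max_mu, n)
  # plain left-to-right double accumulation (sum()/cumsum() accumulate in
  # extended precision, which would break bit-level MU conservation)
  s <- 0
  for (i in seq_len(n - 1L)) s <- s + parts[i]
  parts[n] <- weight - s
  parts
}

# Beam-permission windows for amplitude gating: raw gate is
# y(t) < threshold on the (tiled) trace; permission turns on
# gate_on_buffer after a raw off->on transition and off gate_off_buffer
# after a raw on->off transition. Returns a 2-column matrix [start, end]
# covering [0, horizon]; no gating gives the single window [0, Inf).
gate_windows <- function(trace, threshold, timing, horizon) {
  if (is.null(threshold)) return(matrix(c(0, Inf), 1))
  t <- trace$time - trace$time[1]
  y <- trace$position
  dur <- t[length(t)]
  under <- y < threshold
  # raw under-threshold intervals on one period, via linear interpolation
  starts <- numeric(0); ends <- numeric(0)
  if (under[1]) starts <- 0
  flips <- which(under[-1] != under[-length(under)])
  for (i in flips) {
    tc <- t[i] + (threshold - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
    if (under[i + 1]) starts <- c(starts, tc) else ends <- c(ends, tc)
  }
  if (under[length(under)]) ends <- c(ends, dur)
  if (!length(starts)) return(matrix(numeric(0), 0, 2))
  ntile <- max(1L, ceiling(horizon / dur) + 1L)
  s_all <- rep(starts, ntile) + rep((seq_len(ntile) - 1) * dur, each = length(starts))
  e_all <- rep(ends, ntile) + rep((seq_len(ntile) - 1) * dur, each = length(ends))
  o <- order(s_all); s_all <- s_all[o]; e_all <- e_all[o]
  # merge intervals touching across the tile seam
  ms <- s_all[1]; me <- e_all[1]; outs <- numeric(0); oute <- numeric(0)
  if (length(s_all) > 1) for (i in 2:length(s_all)) {
    if (s_all[i] <= me + 1e-9) me <- max(me, e_all[i])
    else { outs <- c(outs, ms); oute <- c(oute, me); ms <- s_all[i]; me <- e_all[i] }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  # latency buffers; a raw interval beginning at t = 0 has no off->on
  # transition, so the on-buffer does not apply there
  ws <- ifelse(outs <= 1e-12, 0, outs + timing$gate_on_buffer)
  we <- oute + timing$gate_off_buffer
  keep <- we > ws
  cbind(ws[keep], we[keep])
}

#' Beam permission signal
#'
#' Whether the beam is permitted at time(s) `t` under amplitude gating
#' with the machine's gate latency buffers.
#'
#' @param trace A standardized `breathing_trace`.
#' @param t Time(s), s.
#' @param gate A [gate_config()] (or numeric threshold).
#' @param timing A [machine_timing()].
#' @return Logical vector.
#' @export
gate_signal <- function(trace, t, gate, timing = machine_timing()) {
  thr <- if (inherits(gate, "gate_config")) gate$threshold else gate
  win <- gate_windows(trace, thr, timing, max(t) + 1)
  vapply(t, function(ti) {
    any(win[, 1] <= ti & ti < win[, 2])
  }, logical(1))
}

#' Simulate synchrotron spot-scanning delivery
#'
#' Discrete-event simulation of the delivery of a plan: per energy
#' layer, an energy switch plus charge refill, then the repaint passes
#' in serpentine order; per spot, travel from the previous spot
#' (sequential axis moves at the scan and step rates), position
#' verification, and charge spill at the spill rate. The spill pauses
#' whenever beam permission drops (the delivery splits and each
#' sub-interval is stamped with its own temporal midpoint); a refill
#' occurs when stored charge is exhausted or the flat-top hold timer
#' expires.
#'
#' @param plan A `proton_plan` with optimized weights.
#' @param motion A [motion_model()] or `NULL` for a static target.
#' @param timing A [machine_timing()].
#' @param gate A [gate_config()], numeric threshold, or `NULL`.
#' @param repaint A [repaint_config()], numeric max MU, or `NULL`.
#' @param max_time Wall limit, s: the simulation aborts with a
#'   diagnostic (rather than looping forever) if the delivery cannot
#'   finish, e.g. under a never-opening gate.
#' @return A `delivery_timeline`: ordered events with per-event MU,
#'   start/end times, temporal midpoint, and target displacement at the
#'   midpoint (mm).
#' @export
simulate_delivery <- function(plan, motion = NULL,
                              timing = machine_timing(),
                              gate = NULL, repaint = NULL,
                              max_time = 14400) {
  stopifnot(inherits(plan, "proton_plan"), inherits(timing, "machine_timing"))
  thr <- if (inherits(gate, "gate_config")) gate$threshold else gate
  mx <- if (inherits(repaint, "repaint_config")) repaint$max_mu else repaint
  if (is.null(mx)) mx <- Inf
  if (!is.null(thr) && is.null(motion))
    stop_config("amplitude gating requires a motion model (surrogate trace)")

  spots <- plan$spots
  ns <- nrow(spots)
  empty <- data.frame(spot_id = integer(0), layer = integer(0),
                      pass = integer(0), mu = numeric(0),
                      t_start = numeric(0), t_end = numeric(0),
                      t_mid = numeric(0), dx_mm = numeric(0),
                      dy_mm = numeric(0), dz_mm = numeric(0))
  if (!ns)
    return(structure(empty, class = c("delivery_timeline", "data.frame"),
                     total_time = 0, event_log = NULL, timing = timing))
  if (any(spots$weight_mu < timing$min_mu - 1e-9))
    stop_domain("plan contains spots below the minimum deliverable MU")

  parts <- lapply(spots$weight_mu, repaint_partition, max_mu = mx,
                  min_mu = timing$min_mu)
  if (max(vapply(parts, max, 0)) * timing$charge_per_mu >
        timing$charge_capacity)
    stop_config("single delivery exceeds synchrotron charge capacity")
  # cumulative delivery targets per spot: pure double chain, so the
  # ledger of emitted event MUs reproduces the planned weight exactly
  targets <- Map(function(p, w) {
    ct <- Reduce(`+`, p, accumulate = TRUE)
    ct[length(ct)] <- w
    ct
  }, parts, spots$weight_mu)

  # permission windows, lazily extended as the clock advances
  win_env <- new.env(parent = emptyenv())
  win_env$horizon <- 600
  win_env$win <- if (is.null(thr)) matrix(c(0, Inf), 1)
                 else gate_windows(motion$trace, thr, timing, win_env$horizon)
  next_window <- function(t) {
    if (!is.null(thr)) {
      while ((nrow(win_env$win) == 0 ||
              t >= win_env$win[nrow(win_env$win), 2] - 1) &&
             win_env$horizon < 4 * max_time) {
        win_env$horizon <- win_env$horizon * 2
        win_env$win <- gate_windows(motion$trace, thr, timing,
                                    win_env$horizon)
      }
    }
    w <- win_env$win
    i <- which(w[, 2] > t)
    if (!length(i)) return(NULL)
    w[i[1], , drop = FALSE]
  }

  cap <- sum(lengths(parts)) * 2L + 16L
  ev_spot <- integer(cap); ev_layer <- integer(cap); ev_pass <- integer(cap)
  ev_mu <- numeric(cap); ev_t0 <- numeric(cap); ev_t1 <- numeric(cap)
  ne <- 0L
  push <- function(s, l, p, m, t0, t1) {
    ne <<- ne + 1L
    if (ne > length(ev_mu)) {
      grow <- function(v) { length(v) <- 2L * length(v); v }
      ev_spot <<- grow(ev_spot); ev_layer <<- grow(ev_layer)
      ev_pass <<- grow(ev_pass); ev_mu <<- grow(ev_mu)
      ev_t0 <<- grow(ev_t0); ev_t1 <<- grow(ev_t1)
    }
    ev_spot[ne] <<- s; ev_layer[ne] <<- l; ev_pass[ne] <<- p
    ev_mu[ne] <<- m; ev_t0[ne] <<- t0; ev_t1[ne] <<- t1
  }
  log_type <- character(0); log_time <- numeric(0)
  logev <- function(type, tm) {
    log_type <<- c(log_type, type); log_time <<- c(log_time, tm)
  }

  cpm <- timing$charge_per_mu; rate <- timing$spill_rate
  t <- 0; charge <- 0; refill_done <- -Inf
  delivered <- numeric(ns)

  for (li in plan$layers$layer) {
    rows <- which(spots$layer == li)
    t <- t + timing$energy_switch_time  # energy switch + charge refill
    charge <- timing$charge_capacity; refill_done <- t
    logev("layer", t)
    npass <- max(lengths(parts[rows]))
    prev_x <- NA_real_; prev_y <- NA_real_
    for (p in seq_len(npass)) {
      for (s in rows) {
        if (length(parts[[s]]) < p) next
        x <- spots$x_mm[s]; y <- spots$y_mm[s]
        if (!is.na(prev_x))
          t <- t + abs(x - prev_x) / 1000 / timing$scan_rate +
                   abs(y - prev_y) / 1000 / timing$step_rate
        prev_x <- x; prev_y <- y
        t <- t + timing$spot_verification_time
        target <- targets[[s]][p]
        # spill until this pass's cumulative target is reached
        repeat {
          if (t > max_time)
            stop(structure(class = c("proton4d_stall", "error", "condition"),
                           list(message = sprintf(
              "delivery not finished after %.0f s (spot %d, layer %d): gate may never open",
              max_time, s, li), call = NULL)))
          w <- next_window(t)
          if (is.null(w))
            stop(structure(class = c("proton4d_stall", "error", "condition"),
                           list(message =
              "beam permission never granted within the wall limit",
                                call = NULL)))
          if (t < w[1]) {
            logev("wait", t)
            # a refill can run concurrently with the gate-off wait: if the
            # stored charge is (or will be) stale at window start, refill
            # during the wait so the flat-top timer is fresh at beam-on
            if (charge <= 1e-9 ||
                w[1] >= refill_done + timing$charge_hold_time) {
              t <- max(w[1], t + timing$energy_switch_time)
              charge <- timing$charge_capacity; refill_done <- t
              logev("refill", t)
              next
            }
            t <- w[1]
          }
          if (charge <= 1e-9 || t >= refill_done + timing$charge_hold_time) {
            t <- t + timing$energy_switch_time
            charge <- timing$charge_capacity; refill_done <- t
            logev("refill", t)
            next
          }
          remaining <- target - delivered[s]
          dt_need <- remaining * cpm / rate
          limit <- min(w[2], refill_done + timing$charge_hold_time,
                       t + charge / rate)
          if (t + dt_need <= limit + 1e-12) {
            push(s, li, p, remaining, t, t + dt_need)
            charge <- charge - remaining * cpm
            delivered[s] <- target
            t <- t + dt_need
            break
          }
          dt <- limit - t
          if (dt > 1e-12) {
            mu_sub <- dt * rate / cpm
            push(s, li, p, mu_sub, t, limit)
            charge <- charge - mu_sub * cpm
            delivered[s] <- delivered[s] + mu_sub
          }
          t <- limit
        }
      }
    }
  }

  idx <- seq_len(ne)
  tl <- data.frame(spot_id = ev_spot[idx], layer = ev_layer[idx],
                   pass = ev_pass[idx], mu = ev_mu[idx],
                   t_start = ev_t0[idx], t_end = ev_t1[idx])
  tl$t_mid <- (tl$t_start + tl$t_end) / 2
  if (!is.null(motion)) {
    d <- displacement_at(motion, tl$t_mid)
    tl$dx_mm <- d[, 1]; tl$dy_mm <- d[, 2]; tl$dz_mm <- d[, 3]
  } else {
    tl$dx_mm <- 0; tl$dy_mm <- 0; tl$dz_mm <- 0
  }
  structure(tl, class = c("delivery_timeline", "data.frame"),
            total_time = t,
            event_log = data.frame(type = log_type, time = log_time),
            timing = timing,
            planned_mu = spots$weight_mu)
}

#' Total delivery time of a timeline
#'
#' @param timeline A `delivery_timeline`.
#' @return Time in seconds (0 for an empty plan).
#' @export
delivery_time <- function(timeline) {
  attr(timeline, "total_time")
}

#' @export
print.delivery_timeline <- function(x, ...) {
  cat(sprintf(
    "<delivery_timeline> %d events over %d spots, %.2f MU, %.1f s\n",
    nrow(x), length(unique(x$spot_id)), sum(x$mu), delivery_time(x)))
  invisible(x)
}

#' Export a delivery timeline as CSV
#'
#' One row per delivery event: spot id, layer, pass, MU, start/end/mid
#' times (s) and the target displacement at the temporal midpoint (mm).
#'
#' @param timeline A `delivery_timeline`.
#' @param path File path.
#' @param log_path Optional path for the event log (gate waits, refills,
#'   layer switches).
#' @export
write_timeline <- function(timeline, path, log_path = NULL) {
  write.csv(as.data.frame(timeline), path, row.names = FALSE)
  if (!is.null(log_path))
    write.csv(attr(timeline, "event_log"), log_path, row.names = FALSE)
  invisible(path)
}
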