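# Independent oracles, deliberately coded differently from the package.

# Repaint partition in exact integer micro-MU arithmetic, applying the
# delivery rule literally pass by pass: cap at max, absorb a sub-min
# remainder into the preceding pass.
oracle_partition_int <- function(weight_u, max_u, min_u) {
  parts <- integer(0)
  r <- weight_u
  repeat {
    if (r <= max_u) {
      parts <- c(parts, r)
      break
    }
    if (r - max_u < min_u) {        # absorption branch
      parts <- c(parts, r)
      break
    }
    parts <- c(parts, max_u)
    r <- r - max_u
  }
  parts
}

# Step-by-step delivery clock for ungated, static plans: walks the same
# physical rules (energy switch, travel as sequential axis moves,
# verification, spill at constant rate, refill on charge exhaustion or
# flat-top expiry) with straightforward bookkeeping.
oracle_clock <- function(spots, timing, max_mu = Inf) {
  t <- 0
  for (li in sort(unique(spots$layer))) {
    sl <- spots[spots$layer == li, , drop = FALSE]
    parts <- lapply(sl$weight_mu, function(w) {
      out <- numeric(0)
      while (w > max_mu + 1e-9) {
        if (w - max_mu < timing$min_mu - 1e-9) break
        out <- c(out, max_mu)
        w <- w - max_mu
      }
      c(out, w)
    })
    t <- t + timing$energy_switch_time
    charge <- timing$charge_capacity
    refill_t <- t
    px <- NULL; py <- NULL
    for (p in seq_len(max(lengths(parts)))) {
      for (i in seq_len(nrow(sl))) {
        if (length(parts[[i]]) < p) next
        if (!is.null(px))
          t <- t + abs(sl$x_mm[i] - px) / 1000 / timing$scan_rate +
                   abs(sl$y_mm[i] - py) / 1000 / timing$step_rate
        px <- sl$x_mm[i]; py <- sl$y_mm[i]
        t <- t + timing$spot_verification_time
        need <- parts[[i]][p] * timing$charge_per_mu
        while (need > 0) {
          if (charge <= 1e-9 || t >= refill_t + timing$charge_hold_time) {
            t <- t + timing$energy_switch_time
            charge <- timing$charge_capacity
            refill_t <- t
          }
          hold_left <- (refill_t + timing$charge_hold_time) - t
          q <- min(need, charge, hold_left * timing$spill_rate)
          t <- t + q / timing$spill_rate
          charge <- charge - q
          need <- need - q
        }
      }
    }
  }
  t
}

# Hand-rolled plan object around an explicit spot table (unit geometry
# plumbing for delivery tests that do not need dose).
toy_plan <- function(x_mm, y_mm, weight_mu, layer = 1L,
                     geometry = target_geometry()) {
  cfg <- beam_config()
  lay <- sort(unique(layer))
  depths <- 15 + (seq_along(lay) - 1) * 0.5
  structure(list(
    spots = data.frame(layer = layer,
                       energy_mev = range_to_energy(depths[match(layer, lay)]),
                       x_mm = x_mm, y_mm = y_mm, weight_mu = weight_mu),
    layers = data.frame(layer = lay, depth_cm = depths,
                        energy_mev = range_to_energy(depths),
                        sigma_air_mm = 4.9),
    geometry = geometry, spacing_mm = 2.98, layer_spacing_cm = 0.5,
    config = cfg), class = "proton_plan")
}

# Left-to-right plain-double sum (sum() accumulates in extended
# precision, which would mask bit-level conservation failures).
chain_sum <- function(x) Reduce(`+`, x, accumulate = FALSE)
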