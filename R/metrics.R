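#' Cumulative dose-volume histogram
#'
#' Cumulative DVH of a structure: the percentage of the masked volume
#' receiving at least each dose level. The curve is monotone
#' non-increasing and starts at 100% at 0 cGy.
#'
#' @param dose A [dose_grid()] (or a numeric array).
#' @param mask Logical array matching the grid.
#' @param bin_width Dose bin width, cGy (default 0.1).
#' @return A `dvh_result`: data frame with columns `dose` (bin edges,
#'   cGy) and `volume_pct`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.1) {
  vals <- if (inherits(dose, "dose_grid")) dose$values else dose
  if (!any(mask)) stop_domain("empty structure mask")
  if (!all(dim(vals) == dim(mask)))
    stop_domain("mask geometry does not match the dose grid")
  d <- as.vector(vals[mask])
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  n <- length(d)
  # volume fraction receiving >= edge, from the sorted doses
  ds <- sort(d)
  below <- findInterval(edges, ds, left.open = TRUE)  # strictly < edge
  vol <- 100 * (n - below) / n
  structure(data.frame(dose = edges, volume_pct = vol),
            class = c("dvh_result", "data.frame"),
            n_voxels = n)
}

#' @export
print.dvh_result <- function(x, ...) {
  cat(sprintf("<dvh_result> %d voxels, doses up to %.1f cGy\n",
              attr(x, "n_voxels"), max(x$dose)))
  invisible(x)
}

#' @export
plot.dvh_result <- function(x, ..., add = FALSE, col = 1) {
  if (add) graphics::lines(x$dose, x$volume_pct, col = col, ...)
  else graphics::plot(x$dose, x$volume_pct, type = "l", col = col,
                      xlab = "Dose (cGy)", ylab = "Volume (%)", ...)
  invisible(x)
}

# Volume (%) receiving >= level.
volume_at_dose <- function(doses, level) {
  100 * mean(doses >= level)
}

# Dose (cGy) received by at least the hottest q% of the volume:
# linear interpolation between order statistics (the 1 - q/100 quantile).
dose_at_volume <- function(doses, q) {
  p <- 1 - q / 100
  ds <- sort(doses)
  n <- length(ds)
  if (n == 1L) return(ds)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  ds[lo] + (h - lo) * (ds[min(lo + 1, n)] - ds[lo])
}

#' Plan-quality metrics
#'
#' Distills a dose distribution into the scalar plan-quality measures:
#' CTV coverage V97% (volume receiving at least 97% of the
#' prescription), homogeneity index D5% - D95% as a percentage of the
#' prescription, high-dose spillage (volume outside the ITV receiving at
#' least the prescription, cm^3), and total delivery time.
#'
#' @param dose A [dose_grid()].
#' @param ctv_mask,itv_mask Logical arrays matching the grid.
#' @param d_rx Prescription dose, cGy.
#' @param timeline Optional `delivery_timeline`; without it the delivery
#'   time is reported as `NA` (absent, not zero).
#' @return An object of class `plan_quality`: list with `v97`,
#'   `homogeneity_index`, `spillage_cm3`, `delivery_time`.
#' @export
quality_metrics <- function(dose, ctv_mask, itv_mask, d_rx,
                            timeline = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  if (!any(ctv_mask)) stop_domain("empty CTV mask")
  d_ctv <- as.vector(dose$values[ctv_mask])
  v97 <- volume_at_dose(d_ctv, 0.97 * d_rx)
  hi <- (dose_at_volume(d_ctv, 5) - dose_at_volume(d_ctv, 95)) / d_rx * 100
  voxvol <- prod(dose$spacing)
  spill <- voxvol * sum(dose$values >= d_rx & !itv_mask)
  structure(list(v97 = v97, homogeneity_index = hi,
                 spillage_cm3 = spill,
                 delivery_time = if (is.null(timeline)) NA_real_
                                 else delivery_time(timeline)),
            class = "plan_quality")
}

#' @export
print.plan_quality <- function(x, ...) {
  cat(sprintf(
    "<plan_quality> V97 = %.1f%%, HI = %.1f%%, spillage = %.2f cm3, time = %s\n",
    x$v97, x$homogeneity_index, x$spillage_cm3,
    if (is.na(x$delivery_time)) "NA" else sprintf("%.1f s", x$delivery_time)))
  invisible(x)
}

#' Standard error of the mean
#'
#' `sd(x)/sqrt(n)` with the sample (n-1) standard deviation; `NA` for
#' fewer than two values.
#'
#' @param x Numeric vector.
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Motion-mitigation sweep
#'
#' Runs the full simulation chain (delivery timing, 4D accumulation,
#' quality metrics) over a factorial grid of gate levels and maximum-MU
#' repainting thresholds for a set of breathing traces and motion axes,
#' and aggregates the per-trace metrics into means and standard errors
#' across traces. The no-mitigation cell (no gate, no repainting)
#' appears exactly once and is shared by the gate-only and
#' repaint-only series.
#'
#' @param plan An optimized `proton_plan`.
#' @param traces List of standardized `breathing_trace` objects.
#' @param axes Motion axes to simulate.
#' @param gate_levels Gate thresholds, cm.
#' @param max_mu_levels Repainting caps, MU.
#' @param combine_gates Gate levels also crossed with repainting
#'   (default: all but the smallest).
#' @param timing A [machine_timing()].
#' @param config An [accumulation_config()].
#' @param cells Optional data frame with columns `gate`, `max_mu` (NA =
#'   technique off) overriding the default cell grid.
#' @param progress Print one line per simulated cell.
#' @return A `sweep_result`: list with `results` (one row per cell x
#'   axis x trace) and `aggregates` (mean and SEM across traces, with n).
#' @export
run_sweep <- function(plan, traces,
                      axes = c("parallel", "orthogonal"),
                      gate_levels = c(0.75, 0.5, 0.3, 0.2),
                      max_mu_levels = c(0.02, 0.015, 0.01, 0.007, 0.005,
                                        0.004, 0.003, 0.002),
                      combine_gates = NULL,
                      timing = machine_timing(),
                      config = accumulation_config(),
                      cells = NULL, progress = FALSE) {
  stopifnot(inherits(plan, "proton_plan"))
  if (is.null(cells)) {
    if (is.null(combine_gates))
      combine_gates <- gate_levels[-length(gate_levels)]
    cells <- rbind(
      data.frame(gate = NA_real_, max_mu = NA_real_),
      data.frame(gate = gate_levels, max_mu = NA_real_),
      data.frame(gate = NA_real_, max_mu = max_mu_levels),
      expand.grid(gate = combine_gates, max_mu = max_mu_levels))
  }
  geo <- plan$geometry
  grid0 <- build_dose_grid(geo, config)
  ctv <- sphere_mask(grid0, geo$ctv_radius)
  itv <- sphere_mask(grid0, geo$itv_radius)
  if (is.null(names(traces)))
    names(traces) <- paste0("trace", seq_along(traces))

  rows <- list()
  for (ax in axes) {
    for (ci in seq_len(nrow(cells))) {
      g <- cells$gate[ci]; m <- cells$max_mu[ci]
      for (tn in names(traces)) {
        res <- tryCatch({
          mm <- motion_model(traces[[tn]], axis = ax)
          tl <- simulate_delivery(plan, mm, timing,
                                  gate = if (is.na(g)) NULL else g,
                                  repaint = if (is.na(m)) NULL else m)
          dg <- accumulate(tl, plan, config)
          q <- quality_metrics(dg, ctv, itv, geo$prescription, tl)
          data.frame(axis = ax, gate = g, max_mu = m, trace = tn,
                     v97 = q$v97, homogeneity_index = q$homogeneity_index,
                     spillage_cm3 = q$spillage_cm3,
                     delivery_time = q$delivery_time, error = NA_character_)
        }, error = function(e) {
          data.frame(axis = ax, gate = g, max_mu = m, trace = tn,
                     v97 = NA_real_, homogeneity_index = NA_real_,
                     spillage_cm3 = NA_real_, delivery_time = NA_real_,
                     error = conditionMessage(e))
        })
        if (progress)
          message(sprintf("axis=%s gate=%s max_mu=%s %s: V97=%.1f t=%.1f",
                          ax, g, m, tn, res$v97, res$delivery_time))
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- do.call(rbind, rows)
  key <- paste(results$axis,
               ifelse(is.na(results$gate), "none", results$gate),
               ifelse(is.na(results$max_mu), "none", results$max_mu),
               sep = "|")
  agg <- do.call(rbind, lapply(
    split(results, key),
    function(d) {
      data.frame(axis = d$axis[1], gate = d$gate[1], max_mu = d$max_mu[1],
                 n = sum(is.finite(d$v97)),
                 v97_mean = mean(d$v97, na.rm = TRUE),
                 v97_sem = sem(d$v97),
                 hi_mean = mean(d$homogeneity_index, na.rm = TRUE),
                 hi_sem = sem(d$homogeneity_index),
                 spillage_mean = mean(d$spillage_cm3, na.rm = TRUE),
                 spillage_sem = sem(d$spillage_cm3),
                 time_mean = mean(d$delivery_time, na.rm = TRUE),
                 time_sem = sem(d$delivery_time))
    }))
  rownames(agg) <- NULL
  structure(list(results = results, aggregates = agg,
                 geometry = geo), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d simulations, %d cells\n",
              nrow(x$results), nrow(x$aggregates)))
  print(x$aggregates, digits = 4)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, metric = "v97", ...) {
  a <- x$aggregates
  mcol <- paste0(sub("homogeneity_index", "hi", metric), "_mean")
  scol <- sub("_mean$", "_sem", mcol)
  series <- ifelse(is.na(a$gate) & is.na(a$max_mu), "none",
                   ifelse(is.na(a$max_mu), "gating",
                          ifelse(is.na(a$gate), "repainting", "combined")))
  cols <- c(none = 1, gating = 4, repainting = 3, combined = 2)
  graphics::plot(a$time_mean, a[[mcol]], pch = 19, col = cols[series],
                 xlab = "Mean delivery time (s)", ylab = metric, ...)
  graphics::arrows(a$time_mean, a[[mcol]] - a[[scol]], a$time_mean,
                   a[[mcol]] + a[[scol]], angle = 90, code = 3,
                   length = 0.03, col = cols[series])
  graphics::legend("bottomright", legend = names(cols), col = cols, pch = 19,
                   bty = "n")
  invisible(x)
}

#' Write sweep results to CSV
#'
#' One row per simulated cell, followed by the aggregate table in a
#' second file (`*_aggregates.csv`).
#'
#' @param x A `sweep_result`.
#' @param path CSV path for the per-simulation rows.
#' @export
write_sweep <- function(x, path) {
  write.csv(x$results, path, row.names = FALSE)
  agg_path <- sub("\\.csv$", "_aggregates.csv", path)
  if (identical(agg_path, path)) agg_path <- paste0(path, "_aggregates.csv")
  write.csv(x$aggregates, agg_path, row.names = FALSE)
  invisible(path)
}
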