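#' Target geometry
#'
#' Spherical clinical target volume (CTV) with an isotropic internal
#' target volume (ITV) expansion, centered at isocenter.
#'
#' @param ctv_radius CTV radius, cm (default 3).
#' @param itv_margin Isotropic CTV to ITV expansion, cm (default 1).
#' @param center_depth Depth of the target center, cm (default 15).
#' @param prescription Uniform prescription dose to the ITV, cGy
#'   (default 100).
#' @return An object of class `target_geometry` with derived field
#'   `itv_radius`.
#' @export
target_geometry <- function(ctv_radius = 3, itv_margin = 1,
                            center_depth = 15, prescription = 100) {
  check_scalar(ctv_radius, "ctv_radius")
  check_scalar(itv_margin, "itv_margin")
  check_scalar(center_depth, "center_depth")
  check_scalar(prescription, "prescription")
  structure(list(ctv_radius = ctv_radius, itv_margin = itv_margin,
                 itv_radius = ctv_radius + itv_margin,
                 center_depth = center_depth,
                 prescription = prescription),
            class = "target_geometry")
}

#' @export
print.target_geometry <- function(x, ...) {
  cat(sprintf(
    "<target_geometry> CTV r = %g cm, ITV r = %g cm @ %g cm depth, %g cGy\n",
    x$ctv_radius, x$itv_radius, x$center_depth, x$prescription))
  invisible(x)
}

#' Lay out spot positions for a spherical target
#'
#' Places energy layers spanning the ITV in depth (distal to proximal)
#' and, per layer, a square lattice of spots (pitch `spacing`) covering
#' the ITV cross-section at that depth plus a lateral margin. Spots are
#' ordered in serpentine raster order: rows by increasing y, the first
#' row scanning +x and alternating thereafter; the beam only steps in y
#' between sweeps.
#'
#' @param geometry A [target_geometry()].
#' @param config A [beam_config()].
#' @param spacing Lateral spot pitch, mm (default 2.98).
#' @param layer_spacing Depth spacing between energy layers, cm
#'   (default 0.45, giving ~15-20 layers over an 8-cm ITV).
#' @param lateral_margin Margin beyond the ITV contour for spot
#'   placement, mm; defaults to one in-air sigma of the layer's beam.
#' @return A `proton_plan` with unit spot weights.
#' @export
layout_spots <- function(geometry, config = beam_config(),
                         spacing = 2.98, layer_spacing = 0.45,
                         lateral_margin = NULL) {
  stopifnot(inherits(geometry, "target_geometry"))
  check_scalar(spacing, "spacing")
  check_scalar(layer_spacing, "layer_spacing")
  r <- geometry$itv_radius
  d0 <- geometry$center_depth
  # distal to proximal, both poles covered; effective spacing is the
  # closest value <= layer_spacing that divides the span evenly
  nlay <- max(2L, ceiling(2 * r / layer_spacing) + 1L)
  depths <- seq(d0 + r, d0 - r, length.out = nlay)

  layers <- data.frame(layer = seq_along(depths), depth_cm = depths,
                       energy_mev = range_to_energy(depths, config))
  layers$sigma_air_mm <- sigma_air_for_range(depths, config)

  pitch <- spacing / 10  # cm
  spot_list <- lapply(seq_along(depths), function(li) {
    d <- depths[li]
    rho2 <- r^2 - (d - d0)^2
    rho <- sqrt(max(rho2, 0))
    marg <- if (is.null(lateral_margin)) layers$sigma_air_mm[li] / 10
            else lateral_margin / 10
    rmax <- rho + marg
    nmax <- floor(rmax / pitch)
    ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
    x <- ij$i * pitch
    y <- ij$j * pitch
    keep <- x^2 + y^2 <= rmax^2 + 1e-12
    x <- x[keep]; y <- y[keep]
    if (!length(x)) { x <- 0; y <- 0 }  # degenerate cap: central spot
    # serpentine: rows by increasing y; alternate x direction
    ord <- order(y, x)
    x <- x[ord]; y <- y[ord]
    rows <- match(y, sort(unique(y)))
    flip <- rows %% 2 == 0
    for (rw in unique(rows[flip])) {
      idx <- which(rows == rw)
      x[idx] <- rev(x[idx])
    }
    data.frame(layer = li, energy_mev = layers$energy_mev[li],
               x_mm = x * 10, y_mm = y * 10, weight_mu = 1)
  })
  spots <- do.call(rbind, spot_list)
  rownames(spots) <- NULL
  structure(list(spots = spots, layers = layers, geometry = geometry,
                 spacing_mm = spacing, layer_spacing_cm = layer_spacing,
                 config = config),
            class = "proton_plan")
}

#' @export
print.proton_plan <- function(x, ...) {
  cat(sprintf("<proton_plan> %d spots in %d energy layers, pitch %.2f mm\n",
              nrow(x$spots), nrow(x$layers), x$spacing_mm))
  cat(sprintf("  total %.3f MU; depths %.2f-%.2f cm\n", total_mu(x),
              min(x$layers$depth_cm), max(x$layers$depth_cm)))
  invisible(x)
}

#' Total monitor units / spot count of a plan
#'
#' @param plan A `proton_plan`.
#' @return `total_mu`: the exact MU sum; `spots_count`: the number of
#'   spots.
#' @export
total_mu <- function(plan) {
  if (is.null(plan$spots) || !nrow(plan$spots)) return(0)
  sum(plan$spots$weight_mu)
}

#' @rdname total_mu
#' @export
spots_count <- function(plan) {
  if (is.null(plan$spots)) 0L else nrow(plan$spots)
}

# Dose-influence matrix: dose (cGy/MU) of each spot at each point.
# Points are given as columns x, y, z (cm) in the target frame.
influence_matrix <- function(plan, points, geometry_src = source_geometry()) {
  cfg <- plan$config
  n <- nrow(points)
  A <- matrix(0, n, nrow(plan$spots))
  zu <- sort(unique(points$z))
  for (li in seq_len(nrow(plan$layers))) {
    model <- beam_energy_model(range = plan$layers$depth_cm[li],
                               config = cfg,
                               sigma_air = plan$layers$sigma_air_mm[li])
    zmax <- model$range + cfg$distal_margin
    ok <- zu >= 0 & zu <= zmax
    idd_u <- numeric(length(zu))
    sig_u <- rep(1e-3, length(zu))
    idd_u[ok] <- depth_dose(model, zu[ok])
    sig_u[ok] <- lateral_sigma(model, geometry_src, zu[ok]) / 10
    zi <- match(points$z, zu)
    idd <- idd_u[zi]
    sg <- sig_u[zi]
    pri <- (1 - cfg$w) / (2 * pi * sg^2)
    sec <- cfg$w / (2 * pi * (cfg$k * sg)^2)
    rows <- which(plan$spots$layer == li)
    for (s in rows) {
      r2 <- (points$x - plan$spots$x_mm[s] / 10)^2 +
            (points$y - plan$spots$y_mm[s] / 10)^2
      A[, s] <- idd * (pri * exp(-r2 / (2 * sg^2)) +
                       sec * exp(-r2 / (2 * (cfg$k * sg)^2)))
    }
  }
  A
}

#' Nonnegative least-squares weight solve
#'
#' Solves `min ||A w - b||^2 + lambda ||w||^2, w >= 0` by clipped
#' normal-equation iterations: solve on the free set, zero out negative
#' weights, repeat. With `lambda = 0` and a consistent full-rank system
#' the known solution is recovered to numerical precision; a positive
#' `lambda` selects the spread (minimum-norm-like) solution of an
#' underdetermined spot system instead of a sparse vertex solution.
#'
#' @param A Influence matrix (points x spots), nonnegative entries.
#' @param b Target values per point.
#' @param lambda Absolute Tikhonov weight.
#' @param smooth Optional penalty matrix (spots x spots), e.g. a graph
#'   Laplacian over the in-layer spot lattice, added to the normal
#'   equations: it selects smooth per-layer fluence among the many
#'   near-equivalent solutions, as clinical spot-weight regularization
#'   does.
#' @param max_rounds Cap on active-set iterations.
#' @return Nonnegative weight vector.
#' @export
solve_weights <- function(A, b, lambda = 0, smooth = NULL,
                          max_rounds = 60) {
  nsp <- ncol(A)
  free <- rep(TRUE, nsp)
  wgt <- numeric(nsp)
  atb <- crossprod(A, b)
  ata <- crossprod(A)
  if (!is.null(smooth)) ata <- ata + smooth
  ridge <- lambda + 1e-12 * mean(diag(ata))
  for (round in seq_len(max_rounds)) {
    f <- which(free)
    if (!length(f)) stop("weight optimization failure: no free spots left")
    m <- ata[f, f, drop = FALSE]
    diag(m) <- diag(m) + ridge
    wf <- tryCatch(drop(solve(m, atb[f])),
                   error = function(e) {
                     diag(m) <- diag(m) + 1e-6 * mean(diag(m))
                     drop(solve(m, atb[f]))
                   })
    neg <- wf < 0
    wgt[] <- 0
    wgt[f] <- pmax(wf, 0)
    if (!any(neg)) break
    free[f[neg]] <- FALSE
  }
  wgt
}

# Graph Laplacian over the in-layer spot lattice (4-neighbour pitch
# adjacency), used as a smoothness penalty on spot weights.
layer_laplacian <- function(spots, pitch_mm) {
  n <- nrow(spots)
  L <- matrix(0, n, n)
  tol <- 0.05 * pitch_mm
  for (li in unique(spots$layer)) {
    idx <- which(spots$layer == li)
    x <- spots$x_mm[idx]; y <- spots$y_mm[idx]
    for (a in seq_along(idx)) {
      nb <- which((abs(abs(x - x[a]) - pitch_mm) < tol & abs(y - y[a]) < tol) |
                  (abs(abs(y - y[a]) - pitch_mm) < tol & abs(x - x[a]) < tol))
      i <- idx[a]; j <- idx[nb]
      L[i, j] <- L[i, j] - 1
      L[i, i] <- L[i, i] + length(nb)
    }
  }
  L
}

#' Optimize spot weights for uniform ITV coverage
#'
#' Nonnegative least-squares fit of the per-voxel dose inside the ITV to
#' the prescription, on a coarse optimization grid (the evaluation grid
#' can be much finer). Weights below the minimum deliverable MU are
#' pruned and the fit re-run, so every emitted spot is deliverable.
#'
#' @param plan A `proton_plan` (positions laid out).
#' @param opt_spacing Optimization grid spacing, cm (default 0.3).
#' @param min_mu Minimum deliverable MU (default 0.001); spots below it
#'   are removed.
#' @param lambda_rel Tikhonov regularization relative to
#'   `mean(diag(A'A))`. The spot system is underdetermined (more spots
#'   than constraint points); the ridge selects the spread solution a
#'   clinical optimizer produces rather than a sparse vertex solution.
#' @param smooth_rel Within-layer smoothness regularization (graph
#'   Laplacian over the spot lattice) on the same relative scale:
#'   penalizes weight differences between neighboring spots of a layer
#'   so each energy layer delivers a smooth fluence, as clinical
#'   spot-weight regularization does. Set 0 to disable.
#' @param max_rounds Cap on active-set iterations.
#' @return The plan with optimized `weight_mu` (pruned spots removed) and
#'   an `optimization` element holding fit diagnostics.
#' @export
optimize_weights <- function(plan, opt_spacing = 0.3, min_mu = 0.001,
                             lambda_rel = 0.01, smooth_rel = 0.03,
                             max_rounds = 60) {
  stopifnot(inherits(plan, "proton_plan"))
  geo <- plan$geometry
  r <- geo$itv_radius
  ax <- seq(-r, r, by = opt_spacing)
  az <- geo$center_depth + ax
  pts <- expand.grid(x = ax, y = ax, z = az)
  keep <- pts$x^2 + pts$y^2 + (pts$z - geo$center_depth)^2 <= r^2
  pts <- pts[keep, , drop = FALSE]
  # Fibonacci-sampled shell on the ITV surface: the interior lattice
  # stops up to half a spacing short of the contour, which otherwise
  # leaves the surface systematically undercovered
  nsh <- max(200L, ceiling(4 * pi * r^2 / opt_spacing^2))
  i <- seq_len(nsh)
  phi <- pi * (3 - sqrt(5)) * i
  cz <- 1 - 2 * (i - 0.5) / nsh
  sz <- sqrt(pmax(1 - cz^2, 0))
  pts <- rbind(pts, data.frame(x = r * sz * cos(phi), y = r * sz * sin(phi),
                               z = geo$center_depth + r * cz))
  A <- influence_matrix(plan, pts)
  b <- rep(geo$prescription, nrow(pts))
  sc <- mean(colSums(A^2))
  lambda <- lambda_rel * sc
  L <- if (smooth_rel > 0)
    smooth_rel * sc * layer_laplacian(plan$spots, plan$spacing_mm)
  else NULL

  wgt <- solve_weights(A, b, lambda, L, max_rounds)
  for (it in 1:5) {  # prune undeliverable spots, refit survivors
    low <- wgt > 0 & wgt < min_mu
    if (!any(low)) break
    drop_cols <- wgt >= min_mu
    A2 <- A[, drop_cols, drop = FALSE]
    w2 <- solve_weights(A2, b, lambda,
                        if (is.null(L)) NULL
                        else L[drop_cols, drop_cols, drop = FALSE],
                        max_rounds)
    wgt[] <- 0
    wgt[drop_cols] <- w2
  }
  sel <- wgt >= min_mu
  if (!any(sel))
    stop("weight optimization failure: all weights below min_mu; ",
         "check layer spacing / coverage")
  fit <- drop(A[, sel, drop = FALSE] %*% wgt[sel])
  rel_rms <- sqrt(mean((fit - b)^2)) / geo$prescription
  if (rel_rms > 0.05)
    warning(sprintf(
      "weight optimization residual %.1f%% of prescription; coverage may be infeasible (layer spacing too coarse?)",
      100 * rel_rms))
  plan$spots <- plan$spots[sel, , drop = FALSE]
  plan$spots$weight_mu <- wgt[sel]
  rownames(plan$spots) <- NULL
  plan$layers <- plan$layers[plan$layers$layer %in% plan$spots$layer, ,
                             drop = FALSE]
  plan$optimization <- list(opt_spacing = opt_spacing, min_mu = min_mu,
                            n_points = nrow(pts), rel_rms = rel_rms,
                            pruned = sum(!sel))
  plan
}

#' Read/write a plan as a plain-text spot list
#'
#' CSV columns: `layer`, `energy_mev`, `x_mm`, `y_mm`, `weight_mu`. This
#' is also the import path for externally produced plans.
#'
#' @param plan A `proton_plan`.
#' @param path File path.
#' @param geometry,config Geometry/beam configuration to attach on read.
#' @return `read_plan` returns a `proton_plan`.
#' @export
write_plan <- function(plan, path) {
  write.csv(plan$spots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path, geometry = target_geometry(),
                      config = beam_config()) {
  spots <- read.csv(path)
  need <- c("layer", "energy_mev", "x_mm", "y_mm", "weight_mu")
  if (!all(need %in% names(spots)))
    stop_config("plan file must have columns ", paste(need, collapse = ", "))
  lay <- unique(spots[, c("layer", "energy_mev")])
  lay <- lay[order(lay$layer), ]
  layers <- data.frame(layer = lay$layer,
                       depth_cm = energy_to_range(lay$energy_mev, config),
                       energy_mev = lay$energy_mev)
  layers$sigma_air_mm <- sigma_air_for_range(layers$depth_cm, config)
  structure(list(spots = spots, layers = layers, geometry = geometry,
                 spacing_mm = NA_real_, layer_spacing_cm = NA_real_,
                 config = config),
            class = "proton_plan")
}
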