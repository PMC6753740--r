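#' Accumulation configuration
#'
#' Dose-scoring grid settings. The grid is isotropic, centered on the
#' target, and covers the ITV plus `margin` on every side; the default
#' spacing is 0.075 cm (0.75 mm).
#'
#' @param spacing Voxel spacing, cm.
#' @param margin Margin beyond the ITV radius, cm.
#' @return An object of class `accumulation_config`.
#' @export
accumulation_config <- function(spacing = 0.075, margin = 2) {
  check_scalar(spacing, "spacing")
  check_scalar(margin, "margin")
  structure(list(spacing = spacing, margin = margin),
            class = "accumulation_config")
}

#' Build the scoring grid for a target
#'
#' Voxel centers are symmetric about the target center on every axis
#' (odd voxel counts), with `z` the depth axis.
#'
#' @param geometry A [target_geometry()].
#' @param config An [accumulation_config()].
#' @return An empty [dose_grid()].
#' @export
build_dose_grid <- function(geometry, config = accumulation_config()) {
  h <- geometry$itv_radius + config$margin
  n <- 2L * as.integer(round(h / config$spacing)) + 1L
  half <- (n - 1L) / 2 * config$spacing
  origin <- c(-half, -half, geometry$center_depth - half)
  dose_grid(origin, config$spacing, c(n, n, n))
}

#' Spherical structure mask on a grid
#'
#' @param grid A [dose_grid()].
#' @param radius Sphere radius, cm.
#' @param center Sphere center (x, y, z), cm; defaults to the lateral
#'   origin at the grid's central depth.
#' @return Logical array matching the grid.
#' @export
sphere_mask <- function(grid, radius, center = NULL) {
  ax <- grid_axes(grid)
  if (is.null(center))
    center <- c(0, 0, ax$z[(length(ax$z) + 1) / 2])
  dx2 <- (ax$x - center[1])^2
  dy2 <- (ax$y - center[2])^2
  dz2 <- (ax$z - center[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(r2 <= radius^2, dim = grid$dim)
}

# Build per-layer beam models for a plan (cached on the plan's config).
plan_layer_models <- function(plan) {
  lapply(seq_len(nrow(plan$layers)), function(i) {
    beam_energy_model(range = plan$layers$depth_cm[i],
                      config = plan$config,
                      sigma_air = plan$layers$sigma_air_mm[i])
  })
}

#' Accumulate 4D dose from a delivery timeline
#'
#' Rasterizes every delivery event at the lateral position
#' `spot - displacement(t_mid)`, i.e. dose is scored in the target's
#' frame so the static CTV/ITV masks remain valid. Events whose kernel
#' support lies fully outside the grid are clipped; their MU is recorded
#' in the `clipped_mu` attribute and a warning is raised.
#'
#' @param timeline A `delivery_timeline`.
#' @param plan The `proton_plan` that was delivered.
#' @param config An [accumulation_config()].
#' @param geometry Source geometry for the divergence term.
#' @param grid Optional pre-built [dose_grid()] to accumulate into.
#' @return A `dose_grid` of accumulated dose (cGy).
#' @export
accumulate <- function(timeline, plan, config = accumulation_config(),
                       geometry = source_geometry(), grid = NULL) {
  stopifnot(inherits(plan, "proton_plan"))
  if (is.null(grid)) grid <- build_dose_grid(plan$geometry, config)
  vals <- array(grid$values, dim = grid$dim)
  cfg <- plan$config
  clipped <- 0
  for (i in seq_len(nrow(plan$layers))) {
    li <- plan$layers$layer[i]
    ev <- timeline[timeline$layer == li, , drop = FALSE]
    if (!nrow(ev)) next
    model <- beam_energy_model(range = plan$layers$depth_cm[i],
                               config = cfg,
                               sigma_air = plan$layers$sigma_air_mm[i])
    st <- layer_slice_tables(model, geometry, grid)
    sx <- plan$spots$x_mm[ev$spot_id] / 10 - ev$dx_mm / 10
    sy <- plan$spots$y_mm[ev$spot_id] / 10 - ev$dy_mm / 10
    clipped <- clipped +
      cpp_rasterize_events(vals, grid$dim, grid$origin, grid$spacing,
                           sx, sy, ev$mu, st$sigma_cm, st$idd,
                           cfg$w, cfg$k, cfg$trunc_factor)
  }
  if (clipped > 0)
    warning(sprintf("%.4g MU fell fully outside the dose grid (clipped)",
                    clipped))
  grid$values <- vals
  attr(grid, "clipped_mu") <- clipped
  grid
}

#' Static (motion-free) dose of a plan
#'
#' Accumulates the plan with zero displacement for every spot: the
#' reference dose against which 4D simulations are compared.
#'
#' @inheritParams accumulate
#' @return A `dose_grid`.
#' @export
static_dose <- function(plan, config = accumulation_config(),
                        geometry = source_geometry(), grid = NULL) {
  spots <- plan$spots
  tl <- data.frame(spot_id = seq_len(nrow(spots)), layer = spots$layer,
                   pass = 1L, mu = spots$weight_mu,
                   t_start = 0, t_end = 0, t_mid = 0,
                   dx_mm = 0, dy_mm = 0, dz_mm = 0)
  class(tl) <- c("delivery_timeline", "data.frame")
  attr(tl, "total_time") <- 0
  accumulate(tl, plan, config, geometry, grid)
}

#' Read/write dose grids as MetaImage (MHD + RAW)
#'
#' Writes the plain-text `.mhd` header plus a little-endian
#' double-precision `.raw` payload; spacing and offset are stored in mm
#' per the MetaImage convention.
#'
#' @param grid A [dose_grid()].
#' @param path Path of the `.mhd` header; the `.raw` file is written
#'   alongside it.
#' @return `read_mhd` returns a `dose_grid`.
#' @export
write_mhd <- function(grid, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  if (identical(raw_name, basename(path))) raw_name <- paste0(basename(path), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(grid$dim, collapse = " ")),
           paste("ElementSpacing =", paste(grid$spacing * 10, collapse = " ")),
           paste("Offset =", paste(grid$origin * 10, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.vector(grid$values), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_mhd
#' @export
read_mhd <- function(path) {
  hdr <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, " *="), hdr, value = TRUE)[1]
    trimws(sub("^[^=]*=", "", ln))
  }
  dm <- as.integer(strsplit(get("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing"), " +")[[1]]) / 10
  off <- as.numeric(strsplit(get("Offset"), " +")[[1]]) / 10
  raw_file <- file.path(dirname(path), get("ElementDataFile"))
  con <- file(raw_file, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(dm), size = 8, endian = "little")
  dose_grid(off, sp, dm, array(v, dim = dm))
}
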