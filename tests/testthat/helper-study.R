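# Shared scaled-study fixtures, built once per test run on first use.
# Scale: 1.5-cm CTV + 1-cm ITV margin at 15 cm depth, 2-mm scoring grid,
# 10 irregular synthetic traces at nominal 1-cm peak-to-peak.

study_env <- new.env(parent = emptyenv())

study <- function(name) {
  if (!is.null(study_env[[name]])) return(study_env[[name]])
  val <- switch(
    name,
    geometry = target_geometry(ctv_radius = 1.5, itv_margin = 1,
                               center_depth = 15, prescription = 100),
    accum = accumulation_config(spacing = 0.2, margin = 2),
    plan = optimize_weights(
      layout_spots(study("geometry"), layer_spacing = 0.45),
      opt_spacing = 0.3),
    grid = build_dose_grid(study("geometry"), study("accum")),
    ctv_mask = sphere_mask(study("grid"), study("geometry")$ctv_radius),
    itv_mask = sphere_mask(study("grid"), study("geometry")$itv_radius),
    static = static_dose(study("plan"), study("accum")),
    traces = {
      tr <- lapply(1:10, function(i)
        preprocess_trace(synth_trace("irregular", duration = 120,
                                     seed = 100 + i)))
      names(tr) <- paste0("t", 1:10)
      tr
    },
    stop("unknown study fixture: ", name))
  study_env[[name]] <- val
  val
}
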