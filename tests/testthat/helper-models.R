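# Shared model builders.  Equilibria are expensive, so states are memoized
# across test files (testthat runs files in one process, alphabetically).

the_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = the_cache)) assign(key, expr, envir = the_cache)
  get(key, envir = the_cache)
}

# control settings used for all equilibrium runs in the suite: problem sizes
# and tolerances chosen for desk-scale replication (see the methods vignette)
suite_control <- function(...) {
  stabilization_params(cfl = 0.4, tol_ke = 1e-5, tol_f = 5e-4, ...)
}

# small sector for operator and dynamics tests
tiny_model <- function(sector = 8, ...) {
  cache_get(paste0("tiny_", sector), {
    w <- build_wall(wall_geometry(sector_deg = sector), density = 0.24)
    sph_model(w, control = suite_control(), ...)
  })
}

# the study sector (15 deg) at its prestretched reference
ref_model <- function() {
  cache_get("ref15", {
    w <- build_wall(wall_geometry(sector_deg = 15), density = 0.24)
    set_reference(sph_model(w, control = suite_control()))
  })
}

# tone-on equilibria at the evaluation pressures
active_state <- function(pressure) {
  cache_get(paste0("act", pressure), {
    equilibrate_at(ref_model(), pressure = pressure, active = TRUE)
  })
}

# angular half-window equal to one kernel support at mid-media radius (deg)
support_window_deg <- function(model) model$nbr$h / 663 * 180 / pi

# regional max over several lamellae/layers inside a window
region_max <- function(model, kind, idx, lo, hi) {
  max(vapply(idx, function(i)
    tryCatch(regional_max_stress(model, kind, i, lo, hi),
             error = function(e) NA_real_), 0), na.rm = TRUE)
}
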