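# Shared fixtures, built lazily and cached for the whole test run.
# Coarse grids keep the suite fast; resolution-sensitive quantities are
# tested either on smooth oracle problems or with documented tolerances.

.fx <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

fx_template <- function() fx("template", build_template())

fx_npsm_model <- function() fx("npsm_model",
  loft_cochlea(fx_template(), npsm_spec()))

# coarse template volume with canonical electrodes (0.6 mm)
fx_npsm_vol <- function() fx("npsm_vol", {
  vol <- suppressWarnings(voxelize(fx_npsm_model(), spacing = 0.6,
                                   ratio = 1.6))
  suppressWarnings(add_electrode_array(vol,
    canonical_electrode_positions(fx_npsm_model())))
})

# uniform-conductivity grounded sphere with a single central source cell;
# `sigma` applies everywhere (bone label used for every in-sphere cell)
make_sphere_volume <- function(radius = 12, spacing = 0.5) {
  # odd, origin-centered grid: one cell sits exactly at the origin so the
  # source is truly central and the solution mirror-symmetric
  m <- ceiling(radius * 1.05 / spacing)
  cent <- spacing * (-m:m)
  edges <- spacing * c(-m - 0.5, (-m:m) + 0.5)
  n <- length(cent)
  lev <- cochleavc:::LABEL_LEVELS
  lab <- array(match("bone", lev), dim = c(n, n, n))
  r2 <- outer(outer(cent^2, cent^2, "+"), cent^2, "+")
  lab[r2 > radius^2] <- match("exterior", lev)
  ic <- which.min(abs(cent))
  lab[ic, ic, ic] <- match("electrode", lev)
  vol <- structure(list(x = cent, y = cent, z = cent,
                        dx = diff(edges), dy = diff(edges), dz = diff(edges),
                        labels = lab, label_levels = lev,
                        mem_thick = array(NA_real_, dim = c(n, n, n)),
                        spacing = spacing, center = c(0, 0, 0),
                        grounding = grounding_config(radius = radius),
                        spec = npsm_spec(), contact_cells = NULL),
                   class = "labeled_volume")
  vol <- cochleavc:::mark_ground(vol)
  vol$contact_cells <- list(list(
    idx = cochleavc:::cell_index(vol, ic, ic, ic), w = 1))
  vol
}

fx_sphere_field <- function() fx("sphere_field", {
  vol <- make_sphere_volume()
  solve_potential(vol, conductivity_table(), stimulus_config(1, 100))
})

# one coarse synthetic patient with telemetry, shared across files
fx_patient <- function() fx("patient",
  suppressWarnings(generate_patient(1, spacing = 0.8, ratio = 1.7)))

# that patient's (truth-geometry) volume
fx_patient_vol <- function() fx("patient_vol", {
  p <- fx_patient()
  cm <- loft_cochlea(fx_template(), p$spec)
  vol <- suppressWarnings(voxelize(cm, spacing = 0.8, ratio = 1.7))
  suppressWarnings(add_electrode_array(vol, p$array_truth))
})

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
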