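# Shared fixtures, built once per test session and cached in the package's
# own cache environment (so expensive simulations are reused across files).

fx_env <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(fx_env[[name]])) fx_env[[name]] <- build()
  fx_env[[name]]
}

fx_acq <- function(...) {
  acquisition_spec(matrix_size = 48, rng_seed = 1, ...)
}

fx_recon <- function(...) recon_config(broad_beam_scale = 1, ...)

# noiseless dual-threshold calibration curves on the 48^3 demo geometry
fx_curves <- function() {
  fx("curves", function()
    default_curves_for(fx_acq(poisson = FALSE), fx_recon()))
}

# the sphere calibration cells behind fx_curves (for closure tests)
fx_calibration_cells <- function() {
  fx("cal_cells", function() {
    grid <- expand.grid(volume_mL = c(12, 30, 100), sbr = c(2, 8, 32))
    lapply(seq_len(nrow(grid)), function(i)
      simulate_sphere_phantom(grid$volume_mL[i], grid$sbr[i],
                              fx_acq(poisson = FALSE), fx_recon()))
  })
}

fx_kernel_small <- function() fx("kernel6", function()
  build_kernel(half_extent = 6))

# noiseless demonstration study report (full pipeline)
fx_noiseless_report <- function() {
  fx("report0", function()
    run_study(demo_study_config(seed = 1, poisson = FALSE,
                                curves = fx_curves())))
}

# small two-organ phantom on a 48^3 grid for dosimetry tests
fx_dose_phantom <- function() {
  fx("dose_phantom", function()
    build_phantom(pediatric_phantom_spec(age_scale = 0.8, grid_n = 48,
                                         body_mass_g = 25000)))
}

fx_kernel_half <- function() fx("kernel24", function()
  build_kernel(half_extent = 24))

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
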