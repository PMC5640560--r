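# Synthetic phantom, kinetics and acquisition simulator

test_that("sphere region mass matches the closed-form sphere volume", {
  spec <- phantom_spec(
    body = list(half_axes_mm = c(60, 60)),
    regions = list(blob = list(center_mm = c(0, 0, 0),
                               half_axes_mm = rep(14.2, 3), density = 1)),
    grid = list(n = 32, spacing_mm = 4.418))
  ph <- build_phantom(spec)
  m <- ph$masses$mass_g[ph$masses$region == "blob"]
  expect_rel(m, 4 / 3 * pi * 1.42^3, 0.10)  # ~12 g, voxelisation error
})

test_that("disjoint kidneys give two organ labels plus body", {
  spec <- phantom_spec(
    body = list(half_axes_mm = c(80, 80)),
    regions = list(
      left_kidney = list(center_mm = c(-35, 0, 0),
                         half_axes_mm = c(20, 15, 30), density = 1.05),
      right_kidney = list(center_mm = c(35, 0, 0),
                          half_axes_mm = c(20, 15, 30), density = 1.05)),
    grid = list(n = 48, spacing_mm = 4.418))
  ph <- build_phantom(spec)
  expect_setequal(unique(as.vector(unclass(ph$labels))), c(0L, 1L, 2L, 3L))
  expect_false(any(phantom_mask(ph, "left_kidney") &
                     phantom_mask(ph, "right_kidney")))
})

test_that("default pediatric phantom has plausible organ and tumor masses", {
  ph <- build_phantom(pediatric_phantom_spec(grid_n = 96, tumor = TRUE))
  m <- setNames(ph$masses$mass_g, ph$masses$region)
  expect_gt(m[["left_kidney"]] + m[["right_kidney"]], 150)
  expect_lt(m[["left_kidney"]] + m[["right_kidney"]], 350)
  expect_gt(m[["liver"]], 600);  expect_lt(m[["liver"]], 1500)
  expect_gt(m[["spleen"]], 50);  expect_lt(m[["spleen"]], 200)
  expect_gt(m[["tumor_1"]], 14); expect_lt(m[["tumor_1"]], 546)
})

test_that("invalid phantom geometry is rejected with a named error", {
  base <- list(center_mm = c(0, 0, 0), half_axes_mm = c(30, 30, 30),
               density = 1)
  expect_error(build_phantom(phantom_spec(
    body = list(half_axes_mm = c(80, 80)),
    regions = list(a = base, b = modifyList(base, list(center_mm = c(10, 0, 0)))),
    grid = list(n = 48, spacing_mm = 4.418))), "overlapping.*'b' and 'a'")
  expect_error(build_phantom(phantom_spec(
    body = list(half_axes_mm = c(40, 40)),
    regions = list(a = modifyList(base, list(center_mm = c(35, 0, 0)))),
    grid = list(n = 48, spacing_mm = 4.418))), "outside the body")
})

test_that("activity map follows the kinetics model", {
  spec <- phantom_spec(
    body = list(half_axes_mm = c(60, 60)),
    regions = list(blob = list(center_mm = c(0, 0, 0),
                               half_axes_mm = c(30, 30, 30), density = 1)),
    grid = list(n = 32, spacing_mm = 4.418))
  ph <- build_phantom(spec)
  nuc <- nuclide_tc99m()
  # whole activity in one region decaying at the physical rate: one
  # half-life later exactly half the injected activity remains
  kin <- kinetics_spec(100, list(blob = list(f0 = 1,
                                             T_eff_h = nuc$half_life_h)),
                       f_u = 0)
  am <- activity_map(ph, kin, nuc$half_life_h)
  expect_rel(sum(am) / 1e6, 50, 1e-9)
  # f0 = 0.1 at t = 0
  kin2 <- kinetics_spec(100, list(blob = list(f0 = 0.1, T_eff_h = 4)),
                        f_u = 0.5)
  am2 <- activity_map(ph, kin2, 0)
  expect_rel(sum(unclass(am2)[phantom_mask(ph, "blob")]) / 1e6, 10, 1e-9)
  expect_error(activity_map(ph, kin2, -1), "t must be")
})

test_that("uptake-phase peak time matches the closed-form arg-max", {
  # d/dt [ (1 - 2^(-t/Tup)) 2^(-t/Te) ] = 0  =>  t* = Tup log2(1 + Te/Tup)
  Tup <- 0.02; Te <- 4.82
  kin <- kinetics_spec(100, list(k = list(f0 = 0.1, T_eff_h = Te,
                                          T_up_h = Tup)), f_u = 0)
  t_num <- optimize(function(t) region_activity(kin, "k", t),
                    c(0, 0.5), maximum = TRUE)$maximum
  t_closed <- Tup * log2(1 + Te / Tup)
  expect_rel(t_num, t_closed, 1e-3)
  # kidney-like uptake peaks in the 7-10 min window
  expect_gt(t_closed * 60, 7); expect_lt(t_closed * 60, 10)
})

test_that("activity never exceeds the physical-decay bound", {
  kin <- default_kinetics_spec(500)
  ph <- fx_dose_phantom()
  for (t in c(0, 1, 4, 12, 24)) {
    total <- sum(activity_map(ph, kin, t)) / 1e6
    expect_lte(total, 500 * 2^(-t / kin$nuclide$half_life_h) * (1 + 1e-9))
  }
})

test_that("planar projection preserves counts and slab symmetry", {
  n <- 32
  tmpl <- image_volume(array(0, c(n, n, n)), 4.418)
  act <- unclass(tmpl); act[10:20, 12:18, 10:20] <- 5e4
  act <- vol_like(act, tmpl, "Bq")
  acq <- acquisition_spec(matrix_size = n, poisson = FALSE, psf_fwhm_mm = 0,
                          attenuation = FALSE, sensitivity_cps_per_MBq = 100,
                          planar_duration_s = 60)
  pl <- simulate_planar(act, NULL, acq)
  expect_rel(sum(pl$anterior), 100 * 60 * sum(act) / 1e6, 1e-12)
  # uniform slab symmetric about the AP midplane: anterior == posterior
  act2 <- unclass(tmpl); act2[, 14:19, ] <- 1e4
  act2 <- vol_like(act2, tmpl, "Bq")
  mu <- unclass(tmpl); mu[, 14:19, ] <- 0.15
  mu <- vol_like(mu, tmpl, "cm^-1")
  acq2 <- acquisition_spec(matrix_size = n, poisson = FALSE)
  pl2 <- simulate_planar(act2, mu, acq2)
  expect_equal(unclass(pl2$anterior), unclass(pl2$posterior),
               tolerance = 1e-12)
})

test_that("Poisson sampling is seeded, unbiased and reproducible", {
  n <- 32
  tmpl <- image_volume(array(0, c(n, n, n)), 4.418)
  act <- unclass(tmpl); act[16, 16, 16] <- 1e4 / (100 * 60) * 1e6
  act <- vol_like(act, tmpl, "Bq")
  acq <- acquisition_spec(matrix_size = n, poisson = TRUE, psf_fwhm_mm = 6,
                          attenuation = FALSE, sensitivity_cps_per_MBq = 100,
                          planar_duration_s = 60, rng_seed = 11)
  pl <- simulate_planar(act, NULL, acq)
  # expected 1e4 total counts; total within 5 sigma of a Poisson(1e4)
  expect_lt(abs(sum(pl$anterior) - 1e4), 5 * sqrt(1e4))
  pl_again <- simulate_planar(act, NULL, acq)
  expect_identical(unclass(pl$anterior), unclass(pl_again$anterior))
})

test_that("SPECT projector is rotationally consistent and linear", {
  n <- 32
  tmpl <- image_volume(array(0, c(n, n, n)), 4.418)
  ctr <- voxel_centres(tmpl)
  r2 <- outer(outer(ctr[[1]]^2, ctr[[2]]^2, `+`), ctr[[3]]^2, `+`)
  act <- exp(-r2 / (2 * 15^2)) * 1e4   # centred Gaussian blob
  act <- vol_like(act, tmpl, "Bq")
  acq <- acquisition_spec(matrix_size = n, n_projections = 60,
                          poisson = FALSE, attenuation = FALSE)
  proj <- simulate_spect(act, NULL, acq)
  totals <- apply(proj$counts, 3, sum)
  expect_lt(diff(range(totals)) / mean(totals), 0.01)
  expect_rel(mean(totals),
             acq$sensitivity_cps_per_MBq * 20 * sum(act) / 1e6, 1e-3)
  proj2 <- simulate_spect(vol_like(unclass(act) * 3, act), NULL, acq)
  expect_equal(proj2$counts, 3 * proj$counts, tolerance = 1e-12)
})

test_that("forward and backprojector are exact adjoints", {
  n <- 24
  set.seed(5)
  x <- array(runif(n^3), c(n, n, n))
  y <- matrix(runif(n * n), n, n)
  mu <- array(0.05, c(n, n, n))
  Bx <- hybridose:::blur_matrix(n, 1.3)
  for (theta in c(0.3, 1.7, 4.1)) {
    w <- hybridose:::view_attenuation(mu, theta, 4.418)
    Px <- hybridose:::project_view(x, theta, w, Bx, Bx)
    Pty <- hybridose:::backproject_view(y, theta, w, Bx, Bx, c(n, n, n))
    expect_rel(sum(Px * y), sum(x * Pty), 1e-6)
  }
})

test_that("point-source calibration behaves like two ideal heads", {
  acq <- acquisition_spec(matrix_size = 32, poisson = FALSE,
                          sensitivity_cps_per_MBq = 100)
  cal <- simulate_calibration(4.82, 300, acq)
  expect_equal(cal$counts_det1, 144600, tolerance = 1e-9)
  expect_equal(cal$counts_det1, cal$counts_det2)
  expect_error(simulate_calibration(-1, 300, acq), "positive")
  # Poisson round trip: recovered sensitivity within 3 sigma
  acq2 <- acquisition_spec(matrix_size = 32, poisson = TRUE,
                           sensitivity_cps_per_MBq = 150, rng_seed = 3)
  cal2 <- simulate_calibration(4.82, 300, acq2)
  cf <- calibrate(cal2$counts_det1, cal2$counts_det2, 300, 4.82)
  expected_counts <- 150 * 300 * 4.82
  sigma_sens <- 150 / sqrt(2 * expected_counts)
  expect_lt(abs(cf$sensitivity_cps_per_MBq - 150), 3 * sigma_sens)
})

test_that("simulated SPECT data are bit-identical under a fixed seed", {
  ph <- fx_dose_phantom()
  kin <- default_kinetics_spec()
  act <- activity_map(ph, kin, 4)
  acq <- acquisition_spec(matrix_size = 48, n_projections = 20,
                          rng_seed = 9)
  p1 <- simulate_spect(act, ph$mu, acq)
  p2 <- simulate_spect(act, ph$mu, acq)
  expect_identical(p1$counts, p2$counts)
})

test_that("volume and planar round-trip through NIfTI with metadata", {
  v <- image_volume(array(rpois(8^3, 20), c(8, 8, 8)), c(4.418, 4.418, 4.418),
                    units = "Bq")
  path <- file.path(tempdir(), "vol_test.nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_equal(unclass(v2), unclass(v), ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(attr(v2, "spacing"), attr(v, "spacing"))
  expect_equal(attr(v2, "units"), "Bq")
})

test_that("planar pixel dialects resample onto a common grid", {
  img <- planar_image(matrix(rpois(64 * 64, 50), 64, 64), 2.21, time_h = 1)
  out <- resample_planar(img, 4.418)
  expect_equal(attr(out, "spacing"), c(4.418, 4.418))
  # per-area intensities: total counts preserved up to edge effects
  expect_rel(sum(out), sum(img), 0.05)
  expect_identical(resample_planar(img, 2.21), img)
})
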