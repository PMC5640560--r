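# Organ-level MIRD engine: derived S-factors, mass adaptation, sphere model

fx_sfactors <- function() {
  fx("sfactors48", function()
    derive_sfactors(fx_dose_phantom(), fx_kernel_half()))
}

test_that("organ-level doses from derived S-factors match the voxel arm", {
  ph <- fx_dose_phantom()
  ker <- fx_kernel_half()
  tiacs <- c(left_kidney = 0.185, right_kidney = 0.185, liver = 0.56,
             spleen = 0.43, remainder = 5.01)
  dec <- organ_dose_decomposition(cumulated_activity_maps(ph, tiacs), ker)
  od <- organ_doses(tiacs, fx_sfactors())
  cmp <- merge(dec$table, od, by = "region")
  expect_lt(max(abs(cmp$mean_mGy - cmp$dose_mGy_per_MBq) / cmp$mean_mGy),
            0.02)
})

test_that("S table structure: electron cross terms vanish, self dominates", {
  sf <- fx_sfactors()
  S <- sf$S_electron + sf$S_photon
  for (t in rownames(S)) {
    expect_true(all(S[t, ] >= 0))
    expect_true(all(S[t, t] >= S[t, setdiff(colnames(S), t)]))
    for (s in setdiff(rownames(S), t))
      expect_equal(sf$S_electron[t, s], 0)
  }
  # small organs: self dose dominated by the local electron term (1/m
  # beats m^(-2/3) at small mass); the liver is large enough that photon
  # self-absorption catches up
  for (t in c("left_kidney", "right_kidney", "spleen"))
    expect_gt(sf$S_electron[t, t], sf$S_photon[t, t])
})

test_that("distant-pair cross S-factor approximates the point kernel", {
  sf <- fx_sfactors()
  ph <- fx_dose_phantom()
  ker <- fx_kernel_half()
  ctr_of <- function(nm) {
    idx <- which(phantom_mask(ph, nm), arr.ind = TRUE)
    colMeans(idx) * attr(ph$labels, "spacing")
  }
  r_cm <- sqrt(sum((ctr_of("spleen") - ctr_of("left_kidney"))^2)) / 10
  phi <- hybridose:::photon_point_kernel(
    r_cm, hybridose:::photon_lines(nuclide_tc99m(), 1))
  expect_rel(sf$S_photon["spleen", "left_kidney"], phi, 0.25)
})

test_that("mass adaptation scales self terms with the standard exponents", {
  sf <- fx_sfactors()
  same <- adapt_masses(sf, sf$m_ref)
  expect_equal(same$S_electron, sf$S_electron, tolerance = 1e-12)
  expect_equal(same$S_photon, sf$S_photon, tolerance = 1e-12)
  half <- sf$m_ref; half["liver"] <- half["liver"] / 2
  ad <- adapt_masses(sf, half)
  expect_rel(ad$S_electron["liver", "liver"],
             2 * sf$S_electron["liver", "liver"], 1e-12)
  eighth <- sf$m_ref; eighth["spleen"] <- eighth["spleen"] / 8
  ad8 <- adapt_masses(sf, eighth)
  expect_rel(ad8$S_photon["spleen", "spleen"],
             4 * sf$S_photon["spleen", "spleen"], 1e-12)
  # cross terms untouched
  expect_equal(ad8$S_photon["spleen", "liver"],
               sf$S_photon["spleen", "liver"], tolerance = 1e-15)
  expect_error(adapt_masses(sf, c(liver = 100)), "missing")
})

test_that("dose is strictly decreasing in organ mass at fixed TIAC", {
  sf <- fx_sfactors()
  doses <- vapply(c(0.5, 1, 2, 4), function(f) {
    m <- sf$m_ref; m["liver"] <- m["liver"] * f
    od <- organ_doses(c(liver = 0.56), adapt_masses(sf, m))
    od$dose_mGy_per_MBq[od$region == "liver"]
  }, 0)
  expect_true(all(diff(doses) < 0))
})

test_that("MIRD sum is linear with trivial single-source limits", {
  sf <- fx_sfactors()
  d1 <- organ_doses(c(liver = 1), sf)
  S <- sf$S_electron + sf$S_photon
  expect_equal(d1$dose_mGy_per_MBq[d1$region == "liver"],
               S["liver", "liver"], tolerance = 1e-12)
  tiacs <- c(liver = 0.5, spleen = 0.4)
  expect_equal(organ_doses(2 * tiacs, sf)$dose_mGy_per_MBq,
               2 * organ_doses(tiacs, sf)$dose_mGy_per_MBq,
               tolerance = 1e-12)
  expect_error(organ_doses(c(brain = 1), sf), "brain")
})

test_that("sphere-model tumour doses behave like pure self-dose", {
  # electron-only nuclide: dose scales exactly as 1/mass
  nuc <- nuclide_data(6.0067, data.frame(type = "electron",
                                         energy_keV = 100, yield = 1))
  expect_rel(sphere_dose(100, 0.07, nuc), 2 * sphere_dose(200, 0.07, nuc),
             1e-9)
  # the tumour mass range used in pediatric practice is computable
  expect_gt(sphere_dose(14, 0.07), sphere_dose(546, 0.07))
  expect_error(sphere_dose(0.5, 0.07), "range")
  # sphere model omits cross dose: never above the voxel-arm total
  report <- fx_noiseless_report()
  expect_lt(report$doses$sphere_mGy_per_MBq[report$doses$region == "tumor_1"],
            report$doses$voxel_mGy_per_MBq[report$doses$region == "tumor_1"])
})

test_that("pediatric kidney dose sits near reported clinical values", {
  # phantom populated with literature mean TIACs: kidney dose within a
  # factor 2 of 0.026 mGy/MBq
  res <- fx("ped64", function()
    organ_cross_fractions(
      pediatric_phantom_spec(grid_n = 64),
      c(left_kidney = 0.185, right_kidney = 0.185, liver = 0.56,
        spleen = 0.43, remainder = 5.01)))
  kid <- res$table$mean_mGy[res$table$region == "left_kidney"]
  expect_gt(kid, 0.026 / 2)
  expect_lt(kid, 0.026 * 2)
})
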