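# Voxel S-value kernel, FFT dose maps, self/cross decomposition, DVHs

test_that("electron-only kernel centre matches hand unit conversion", {
  nuc <- nuclide_data(6.0067, data.frame(type = "electron",
                                         energy_keV = 100, yield = 0.5))
  ker <- build_kernel(nuc, voxel_mm = 4.418, half_extent = 2)
  m_vox_kg <- (0.4418)^3 / 1000          # 8.626e-5 kg
  k0_hand <- 0.1 * 0.5 * 1.602176634e-13 * 3.6e9 / m_vox_kg * 1e3
  expect_rel(ker$k[3, 3, 3], k0_hand, 1e-12)
  expect_equal(sum(ker$k) - ker$k[3, 3, 3], 0)   # no photon component
})

test_that("kernel is central-symmetric with its maximum at the origin", {
  ker <- fx_kernel_small()
  c0 <- ker$half_extent + 1
  expect_equal(ker$k[c0 + 1, c0 + 2, c0 + 3], ker$k[c0 - 1, c0 - 2, c0 - 3],
               tolerance = 1e-15)
  expect_true(all(ker$k >= 0))
  expect_equal(which.max(ker$k),
               c0 + (c0 - 1) * dim(ker$k)[1] + (c0 - 1) * prod(dim(ker$k)[1:2]))
})

test_that("kernel energy bookkeeping agrees with the radial oracle", {
  ker <- fx_kernel_half()
  R <- ker$half_extent * ker$voxel_mm / 10
  grid_J <- kernel_absorbed_energy(ker, R)
  oracle_J <- kernel_absorbed_energy_oracle(nuclide_tc99m(), R)
  expect_gt(grid_J / oracle_J, 0.9)
  expect_lt(grid_J / oracle_J, 1.05)
  # and never exceeds the total emitted energy per MBq.h
  total_J <- 3.6e9 * energy_per_decay_mev(nuclide_tc99m()) * 1.602176634e-13
  expect_lt(kernel_absorbed_energy(ker, Inf), total_J)
})

test_that("kernel grid refinement is numerically stable", {
  R <- 6 * 0.4418  # cm
  coarse <- kernel_absorbed_energy(build_kernel(voxel_mm = 4.418,
                                                half_extent = 6), R)
  fine <- kernel_absorbed_energy(build_kernel(voxel_mm = 2.209,
                                              half_extent = 12), R)
  expect_rel(fine, coarse, 0.02)
})

test_that("dose map is the impulse response and is linear", {
  ker <- fx_kernel_small()
  a <- array(0, c(15, 15, 15)); a[8, 8, 8] <- 1
  av <- image_volume(a, 4.418, units = "MBq.h")
  d <- dose_map(av, ker)
  c0 <- 8; h <- ker$half_extent
  expect_equal(unclass(d)[(c0 - h):(c0 + h), (c0 - h):(c0 + h),
                          (c0 - h):(c0 + h)],
               ker$k, tolerance = 1e-12, ignore_attr = TRUE)
  d2 <- dose_map(vol_like(2 * unclass(av), av), ker)
  expect_equal(unclass(d2), 2 * unclass(d), tolerance = 1e-12)
  expect_error(dose_map(image_volume(a, 2), ker), "mismatch")
})

test_that("FFT convolution matches the brute-force double sum", {
  set.seed(12)
  ker <- fx_kernel_small()
  av <- image_volume(array(runif(12^3), c(12, 12, 12)), 4.418,
                     units = "MBq.h")
  d_fft <- dose_map(av, ker)
  d_bf <- dose_map_bruteforce(av, ker)
  expect_lt(max(abs(d_fft - d_bf)) / max(d_bf), 1e-9)
})

test_that("self/cross decomposition is exact and complete", {
  ker <- fx_kernel_small()
  dims <- c(20, 20, 20)
  # two point sources: cross dose at A from B is the kernel at their offset
  aA <- array(0, dims); aA[8, 10, 10] <- 1
  aB <- array(0, dims); aB[13, 10, 10] <- 2
  maps <- list(A = image_volume(aA, 4.418, units = "MBq.h"),
               B = image_volume(aB, 4.418, units = "MBq.h"))
  masks <- list(A = aA > 0, B = aB > 0)
  dec <- organ_dose_decomposition(maps, ker, masks)
  tab <- dec$table
  h <- ker$half_extent + 1
  expect_equal(tab$cross_mGy[tab$region == "A"], 2 * ker$k[h + 5, h, h],
               tolerance = 1e-12)
  expect_equal(tab$self_mGy + tab$cross_mGy, tab$mean_mGy,
               tolerance = 1e-15)
  # single-organ phantom: no cross dose
  dec1 <- organ_dose_decomposition(maps["A"], ker, masks["A"])
  expect_equal(dec1$table$cross_mGy, 0, tolerance = 1e-15)
})

test_that("DVHs are proper survival curves that reproduce the mean", {
  ker <- fx_kernel_small()
  set.seed(4)
  av <- image_volume(array(runif(16^3), c(16, 16, 16)), 4.418,
                     units = "MBq.h")
  d <- dose_map(av, ker)
  mask <- array(FALSE, dim(d)); mask[4:12, 4:12, 4:12] <- TRUE
  h <- dvh(d, mask, n_bins = 200)
  expect_equal(h$fraction[1], 1)
  expect_true(all(diff(h$fraction) <= 0))
  bin_w <- diff(h$dose)[1]
  expect_lt(abs(dvh_mean(h) - mean(d[mask])), bin_w)
  # uniform dose: a step function through 0.5 at the dose value
  du <- vol_like(array(5, dim(d)), d)
  hu <- dvh(du, mask, n_bins = 10)
  expect_true(all(hu$fraction == 1))
  expect_error(dvh(d, array(FALSE, dim(d))), "empty")
})

test_that("energy in a dose map is conserved up to boundary escape", {
  ker <- fx_kernel_half()
  dims <- c(49, 49, 49)
  a <- array(0, dims); a[25, 25, 25] <- 1   # centred 1 MBq.h point
  d <- dose_map(image_volume(a, 4.418, units = "MBq.h"), ker)
  m_vox_kg <- (0.4418)^3 / 1000
  in_map_J <- sum(d) * m_vox_kg / 1000
  total_J <- 3.6e9 * energy_per_decay_mev(nuclide_tc99m()) * 1.602176634e-13
  expect_lt(in_map_J, total_J)
  expect_gt(in_map_J / kernel_absorbed_energy(ker, Inf), 1 - 1e-9)
})
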