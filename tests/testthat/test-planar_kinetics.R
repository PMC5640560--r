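# Planar ROI extraction, registration and mono-exponential fitting

mk_img <- function(m, spacing = 4.418, t = 1) planar_image(m, spacing, time_h = t)

test_that("ROI50 keeps pixels at or above half of the regional maximum", {
  img <- mk_img(matrix(c(10, 5, 4, 0), 2, 2))
  mask <- matrix(TRUE, 2, 2)
  roi <- make_roi50(img, mask)
  expect_equal(which(roi$mask), which(unclass(img) >= 5))
  # uniform region: the whole mask survives
  img2 <- mk_img(matrix(7, 4, 4))
  expect_true(all(make_roi50(img2, matrix(TRUE, 4, 4))$mask))
  expect_error(make_roi50(mk_img(matrix(0, 3, 3)), matrix(TRUE, 3, 3)),
               "no signal")
})

test_that("ROI50 area of a Gaussian blob matches the half-max disk", {
  n <- 101
  sigma <- 8
  g <- outer(seq_len(n) - 51, seq_len(n) - 51,
             function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  roi <- make_roi50(mk_img(g, spacing = 1), matrix(TRUE, n, n))
  r_half <- sigma * sqrt(2 * log(2))
  expect_rel(sum(roi$mask), pi * r_half^2, 0.05)
})

test_that("ROI propagation recovers rigid shifts and ignores global scale", {
  set.seed(2)
  base <- matrix(0, 40, 40)
  base[15:22, 18:24] <- 50
  base <- base + matrix(runif(1600, 0, 2), 40, 40)
  imgs <- list(mk_img(base, t = 1),
               mk_img(base, t = 2),           # identical
               mk_img(0.5 * base, t = 3))     # decayed
  shifted <- matrix(0, 40, 40)
  shifted[(15:22) + 3, (18:24) - 2] <- 50
  imgs[[4]] <- mk_img(shifted, t = 4)
  roi <- make_roi50(imgs[[1]], base > 10)
  out <- propagate_roi(roi, imgs)
  expect_equal(out[[2]]$shift, c(0, 0))
  expect_equal(out[[3]]$shift, c(0, 0))
  expect_equal(out[[4]]$shift, c(3, -2))
  expect_false(out[[4]]$at_edge)
})

test_that("background subtraction is geometric and floored at zero", {
  img <- mk_img(matrix(0, 20, 20))
  roi_mask <- matrix(FALSE, 20, 20); roi_mask[1:5, 1:10] <- TRUE  # 50 px
  bg_mask <- matrix(FALSE, 20, 20); bg_mask[10:12, 1:10] <- TRUE
  img[roi_mask] <- 20           # total 1000
  img[bg_mask] <- 4
  roi <- set_roi_background(list(label = "r", mask = roi_mask), bg_mask)
  b <- background_corrected_counts(img, roi)
  expect_equal(b$corrected, 1000 - 4 * 50)
  img[bg_mask] <- 0
  expect_equal(background_corrected_counts(img, roi)$corrected, b$raw)
  img[bg_mask] <- 100
  over <- background_corrected_counts(img, roi)
  expect_equal(over$corrected, 0)
  expect_true(over$clipped)
  expect_error(background_corrected_counts(img, list(mask = roi_mask,
                                                     background = NULL)),
               "background")
})

test_that("two-point fits are exact and the T_bio relation holds", {
  nuc <- nuclide_tc99m()
  tac <- data.frame(t_h = c(1, 5), counts = c(100, 50))
  fit <- fit_monoexponential(tac, nuc)
  expect_equal(fit$T_eff_h, 4, tolerance = 1e-12)
  # symmetry point: T_eff = T_phys/2  =>  T_bio = T_phys
  expect_rel(biological_half_life(nuc$half_life_h / 2), nuc$half_life_h,
             1e-12)
  # spleen-like accumulation: T_eff above T_phys gives a negative T_bio
  tac2 <- data.frame(t_h = c(1, 5), counts = 100 * 2^(-c(1, 5) / 8.22))
  fit2 <- fit_monoexponential(tac2, nuc)
  expect_rel(fit2$T_eff_h, 8.22, 1e-9)
  expect_lt(fit2$T_bio_h, 0)
  expect_true("accumulation" %in% fit2$flags)
  # equality reported as an infinite sentinel
  expect_identical(biological_half_life(nuc$half_life_h), Inf)
})

test_that("T_bio is monotone decreasing in T_eff and diverges at T_phys", {
  nuc <- nuclide_tc99m()
  te <- seq(0.5, nuc$half_life_h - 1e-3, length.out = 50)
  tb <- biological_half_life(te)
  expect_true(all(diff(tb) > 0))  # 1/T_bio decreasing => T_bio increasing
  expect_gt(biological_half_life(nuc$half_life_h - 1e-6), 1e6)
})

test_that("fits recover generator parameters, noiseless and under Poisson", {
  nuc <- nuclide_tc99m()
  set.seed(31)
  for (i in 1:20) {
    A0 <- runif(1, 1e3, 1e5); Te <- runif(1, 2, 6)
    ts <- sort(runif(3, 0.5, 23))
    tac <- data.frame(t_h = ts, counts = A0 * 2^(-ts / Te))
    fit <- fit_monoexponential(tac, nuc)
    expect_rel(fit$T_eff_h, Te, 1e-9)
    expect_rel(fit$A0, A0, 1e-9)
  }
  # Poisson at >= 1e4 ROI counts: T_eff within 15% in at least 95% of runs
  ok <- vapply(1:200, function(s) {
    set.seed(s)
    ts <- c(1.5, 5, 22)
    counts <- rpois(3, 2e4 * 2^(-ts / 4.7))
    fit <- fit_monoexponential(data.frame(t_h = ts, counts = counts), nuc)
    abs(fit$T_eff_h - 4.7) / 4.7 <= 0.15
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate TACs are excluded or rejected", {
  nuc <- nuclide_tc99m()
  expect_warning(
    fit <- fit_monoexponential(
      data.frame(t_h = c(1, 3, 5), counts = c(100, 0, 25)), nuc),
    "excluded")
  expect_rel(fit$T_eff_h, 2, 1e-9)
  expect_error(suppressWarnings(fit_monoexponential(
    data.frame(t_h = c(1, 3), counts = c(100, 0)), nuc)), "at least 2")
  expect_error(fit_monoexponential(
    data.frame(t_h = c(1, 5), counts = c(50, 100)), nuc), "washout")
})
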