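#' Acquisition specification
#'
#' Geometry and counting parameters of the simulated gamma camera. Defaults
#' mirror a typical clinical protocol: 60 projections of 20 s over a 360
#' degree circular orbit on a 128 x 128 matrix with 4.418 mm pixels, and
#' 2-3 whole-body planar sweeps within 24 h of injection.
#'
#' @param n_projections number of SPECT views over 360 degrees.
#' @param seconds_per_projection dwell time per view (s).
#' @param matrix_size SPECT matrix dimension (in-plane, square).
#' @param pixel_mm SPECT pixel/voxel size (mm).
#' @param planar_times_h planar scan times post-injection (h), strictly
#'   increasing, within (0, 24].
#' @param spect_time_h SPECT acquisition time post-injection (h).
#' @param planar_duration_s effective planar acquisition duration (s); the
#'   acquisition duration of a whole-body sweep is protocol-dependent, so it
#'   is a free parameter here.
#' @param planar_pixel_mm planar pixel size (mm); `NULL` keeps the volume
#'   grid spacing. Clinical dialects are 2.21 or 2.88 mm.
#' @param sensitivity_cps_per_MBq system sensitivity per detector head.
#' @param psf_fwhm_mm FWHM of the distance-independent Gaussian detector
#'   response.
#' @param attenuation apply attenuation in the forward model.
#' @param poisson apply Poisson counting noise.
#' @param rng_seed seed used for Poisson sampling; identical seed and spec
#'   give bit-identical simulated data.
#' @export
acquisition_spec <- function(n_projections = 60, seconds_per_projection = 20,
                             matrix_size = 128, pixel_mm = 4.418,
                             planar_times_h = c(1.5, 5, 22),
                             spect_time_h = 4,
                             planar_duration_s = 180,
                             planar_pixel_mm = NULL,
                             sensitivity_cps_per_MBq = 90,
                             psf_fwhm_mm = 10,
                             attenuation = TRUE, poisson = TRUE,
                             rng_seed = 1L) {
  stopifnot(n_projections > 0, seconds_per_projection > 0,
            sensitivity_cps_per_MBq > 0, psf_fwhm_mm >= 0,
            planar_duration_s > 0)
  if (is.unsorted(planar_times_h, strictly = TRUE) ||
      any(planar_times_h <= 0) || any(planar_times_h > 24))
    stop("planar_times_h must be strictly increasing within (0, 24] h")
  structure(list(n_projections = as.integer(n_projections),
                 seconds_per_projection = seconds_per_projection,
                 matrix_size = as.integer(matrix_size), pixel_mm = pixel_mm,
                 planar_times_h = planar_times_h, spect_time_h = spect_time_h,
                 planar_duration_s = planar_duration_s,
                 planar_pixel_mm = planar_pixel_mm,
                 sensitivity_cps_per_MBq = sensitivity_cps_per_MBq,
                 psf_fwhm_mm = psf_fwhm_mm, attenuation = attenuation,
                 poisson = poisson, rng_seed = rng_seed),
            class = "acquisition_spec")
}

# ---- linear operators ----------------------------------------------------

# sparse bilinear in-plane rotation operator on an n x n grid (about centre);
# its transpose is the exact adjoint used for backprojection
rotation_operator <- function(n, theta) {
  key <- sprintf("rot_%d_%.10f", n, theta)
  cache_get(key, function() {
    c0 <- (n + 1) / 2
    idx <- seq_len(n)
    gx <- rep(idx, times = n) - c0
    gy <- rep(idx, each = n) - c0
    ct <- cos(theta); st <- sin(theta)   # sample source at R(-theta) * target
    sx <- ct * gx + st * gy + c0
    sy <- -st * gx + ct * gy + c0
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    rows <- integer(0); cols <- integer(0); w <- numeric(0)
    for (dx in 0:1) for (dy in 0:1) {
      xs <- x0 + dx; ys <- y0 + dy
      wt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy)
      ok <- xs >= 1 & xs <= n & ys >= 1 & ys <= n & wt > 0
      rows <- c(rows, which(ok))
      cols <- c(cols, xs[ok] + (ys[ok] - 1) * n)
      w <- c(w, wt[ok])
    }
    Matrix::sparseMatrix(i = rows, j = cols, x = w, dims = c(n * n, n * n))
  })
}

# apply an n^2 x n^2 operator slice-wise to a (n, n, nz) array
apply_inplane <- function(arr, op) {
  d <- dim(arr)
  array(as.matrix(op %*% matrix(arr, d[1] * d[2], d[3])), d)
}

# symmetric Gaussian convolution matrix with zero padding (self-adjoint)
blur_matrix <- function(n, sigma_px) {
  if (sigma_px <= 1e-9) return(NULL)
  key <- sprintf("blur_%d_%.8f", n, sigma_px)
  cache_get(key, function() {
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    B <- exp(-d^2 / (2 * sigma_px^2))
    # normalise so that an interior impulse keeps unit sum
    B / sum(exp(-(seq(-n, n))^2 / (2 * sigma_px^2)))
  })
}

blur2d <- function(img, Bx, Bz) {
  if (!is.null(Bx)) img <- Bx %*% img
  if (!is.null(Bz)) img <- img %*% Bz   # Bz symmetric
  as.matrix(img)
}

# cumulative attenuation factor along dim 2 towards the detector at j = 1,
# half-voxel convention inside the current voxel; mu in cm^-1, dy in mm
attenuation_factors <- function(mu_arr, dy_mm) {
  d <- dim(mu_arr)
  cs <- mu_arr
  if (d[2] > 1) for (j in 2:d[2]) cs[, j, ] <- cs[, j, ] + cs[, j - 1, ]
  exp(-(cs - 0.5 * mu_arr) * dy_mm / 10)
}

# sum along dim 2 of a (nx, ny, nz) array -> (nx, nz) matrix
sum_depth <- function(arr) {
  d <- dim(arr)
  colSums(aperm(arr, c(2, 1, 3)), dims = 1)
}

# expand a detector image back along dim 2 with per-voxel weights
expand_depth <- function(img, weights) {
  d <- dim(weights)
  weights * aperm(array(img, c(d[1], d[3], d[2])), c(1, 3, 2))
}

psf_sigma_px <- function(fwhm_mm, pixel_mm) fwhm_mm / 2.3548200450309493 / pixel_mm

# single-view geometric forward projection (no sensitivity/time scaling):
# rotate the volume so the detector looks along dim 2, attenuate, sum, blur
project_view <- function(act_arr, theta, att_w, Bx, Bz) {
  ar <- if (theta != 0) apply_inplane(act_arr, rotation_operator(dim(act_arr)[1], theta)) else act_arr
  if (!is.null(att_w)) ar <- ar * att_w
  blur2d(sum_depth(ar), Bx, Bz)
}

# exact adjoint of project_view
backproject_view <- function(img, theta, att_w, Bx, Bz, dims) {
  img <- blur2d(img, Bx, Bz)
  ar <- if (is.null(att_w)) expand_depth(img, array(1, dims))
  else expand_depth(img, att_w)
  if (theta != 0)
    ar <- apply_inplane(ar, Matrix::t(rotation_operator(dims[1], theta)))
  ar
}

# rotated attenuation weights for one view (NULL when attenuation off)
view_attenuation <- function(mu_arr, theta, dy_mm) {
  if (is.null(mu_arr)) return(NULL)
  mr <- if (theta != 0) apply_inplane(mu_arr, rotation_operator(dim(mu_arr)[1], theta)) else mu_arr
  attenuation_factors(mr, dy_mm)
}

# ---- simulators ----------------------------------------------------------

#' Simulate an anterior/posterior planar scan pair
#'
#' Parallel-ray projection of the activity volume along the
#' anterior-posterior axis (array dim 2; anterior detector at index 1) with
#' exponential attenuation, Gaussian detector blur, scaling by sensitivity
#' and duration, and optional Poisson sampling.
#'
#' @param activity an `image_volume` in Bq.
#' @param mu attenuation map (cm^-1) on the same grid, or `NULL`.
#' @param acq an [acquisition_spec()].
#' @param time_h time stamp attached to the output images.
#' @return list with `anterior` and `posterior` [planar_image()]s (counts).
#' @export
simulate_planar <- function(activity, mu, acq, time_h = NA_real_) {
  sp <- attr(activity, "spacing")
  if (!is.null(mu) && acq$attenuation) {
    if (!isTRUE(all.equal(attr(mu, "spacing"), sp)) ||
        !identical(dim(mu), dim(activity)))
      stop("activity and attenuation grids differ")
    mu_arr <- unclass(mu)
  } else mu_arr <- NULL
  a <- unclass(activity) / 1e6   # MBq
  d <- dim(a)
  Bx <- blur_matrix(d[1], psf_sigma_px(acq$psf_fwhm_mm, sp[1]))
  Bz <- blur_matrix(d[3], psf_sigma_px(acq$psf_fwhm_mm, sp[3]))
  scale <- acq$sensitivity_cps_per_MBq * acq$planar_duration_s
  ant_w <- if (!is.null(mu_arr)) attenuation_factors(mu_arr, sp[2]) else NULL
  ant <- blur2d(sum_depth(if (is.null(ant_w)) a else a * ant_w), Bx, Bz) * scale
  flip <- function(x) x[, dim(x)[2]:1, , drop = FALSE]
  post_w <- if (!is.null(mu_arr)) flip(attenuation_factors(flip(mu_arr), sp[2])) else NULL
  post <- blur2d(sum_depth(if (is.null(post_w)) a else a * post_w), Bx, Bz) * scale
  if (acq$poisson) {
    cnt <- with_seed(acq$rng_seed, {
      c(stats::rpois(length(ant), pmax(ant, 0)),
        stats::rpois(length(post), pmax(post, 0)))
    })
    ant <- matrix(cnt[seq_along(ant)], nrow(ant))
    post <- matrix(cnt[length(ant) + seq_along(post)], nrow(post))
  }
  out_sp <- sp[c(1, 3)]
  ant <- planar_image(ant, out_sp, "counts", time_h)
  post <- planar_image(post, out_sp, "counts", time_h)
  if (!is.null(acq$planar_pixel_mm)) {
    ant <- resample_planar(ant, acq$planar_pixel_mm)
    post <- resample_planar(post, acq$planar_pixel_mm)
  }
  list(anterior = ant, posterior = post)
}

#' Simulate a SPECT projection set
#'
#' Rotation-based parallel-beam forward projection over a 360 degree
#' circular orbit with attenuation, a distance-independent Gaussian PSF and
#' Poisson noise. The projector and its transpose form a matched
#' projector/backprojector pair, shared with [osem_reconstruct()].
#'
#' @inheritParams simulate_planar
#' @return A `projection_set`: list with `counts` (array view x, axial z,
#'   view index), `angles_rad`, `acq`.
#' @export
simulate_spect <- function(activity, mu, acq) {
  sp <- attr(activity, "spacing")
  d <- dim(activity)
  if (d[1] != d[2]) stop("SPECT simulation needs nx == ny")
  a <- unclass(activity) / 1e6
  mu_arr <- if (!is.null(mu) && acq$attenuation) unclass(mu) else NULL
  nv <- acq$n_projections
  angles <- 2 * pi * (seq_len(nv) - 1) / nv
  Bx <- blur_matrix(d[1], psf_sigma_px(acq$psf_fwhm_mm, sp[1]))
  Bz <- blur_matrix(d[3], psf_sigma_px(acq$psf_fwhm_mm, sp[3]))
  scale <- acq$sensitivity_cps_per_MBq * acq$seconds_per_projection
  counts <- array(0, c(d[1], d[3], nv))
  for (v in seq_len(nv)) {
    w <- view_attenuation(mu_arr, angles[v], sp[2])
    counts[, , v] <- project_view(a, angles[v], w, Bx, Bz) * scale
  }
  if (acq$poisson)
    counts <- with_seed(acq$rng_seed,
                        array(stats::rpois(length(counts), pmax(counts, 0)),
                              dim(counts)))
  structure(list(counts = counts, angles_rad = angles, acq = acq,
                 spacing = sp, dims = d), class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d views, %d x %d, total %.6g counts\n",
              length(x$angles_rad), dim(x$counts)[1], dim(x$counts)[2],
              sum(x$counts)))
  invisible(x)
}

#' Write a projection set to NIfTI plus a JSON angle sidecar
#' @param x a `projection_set`.
#' @param path output path (`.nii.gz`).
#' @export
write_projections <- function(x, path) {
  img <- RNifti::asNifti(x$counts)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(angles_rad = x$angles_rad, spacing = x$spacing,
                            dims = x$dims,
                            acq = x$acq[setdiff(names(x$acq), "rng_seed")]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a point-source calibration acquisition
#'
#' A small vial in air centred between the two detector heads; each head
#' records `sensitivity x duration x activity` expected counts, Poisson
#' sampled when noise is on.
#'
#' @param activity_MBq vial activity (MBq), > 0.
#' @param duration_s acquisition duration (s).
#' @param acq an [acquisition_spec()].
#' @return list with `counts_det1`, `counts_det2`, `duration_s`,
#'   `activity_MBq`.
#' @export
simulate_calibration <- function(activity_MBq, duration_s, acq) {
  if (activity_MBq <= 0) stop("calibration activity must be positive")
  expected <- acq$sensitivity_cps_per_MBq * duration_s * activity_MBq
  cnt <- if (acq$poisson)
    with_seed(acq$rng_seed, stats::rpois(2L, expected))
  else rep(expected, 2L)
  list(counts_det1 = cnt[1], counts_det2 = cnt[2],
       duration_s = duration_s, activity_MBq = activity_MBq)
}
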