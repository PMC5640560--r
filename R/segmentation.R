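#' Dual adaptive-threshold calibration curves
#'
#' The dual iterative adaptive thresholding method uses two calibration
#' curves, fitted on sphere-in-background phantom reconstructions: one
#' threshold (percent of the regional maximum) recovers the true object
#' volume, the other the true activity, each as a function of the observed
#' signal-to-background ratio (SBR). The functional form is
#' `T(SBR) = a + b / SBR`. Because the curves are built through the same
#' reconstruction pipeline that produces patient images, they implicitly
#' absorb partial-volume effects; for objects larger than about 12 mL the
#' thresholds are insensitive to object size.
#'
#' @name calibration_curves
NULL

#' Simulate and reconstruct a sphere-in-background calibration phantom
#'
#' A uniform sphere of the requested volume, centred in a warm cylindrical
#' background at the requested SBR (activity concentration ratio), pushed
#' through [simulate_spect()] and [osem_reconstruct()] and converted to
#' activity with an ideal calibration factor.
#'
#' @param volume_mL sphere volume (>= 12 mL for validity of the method).
#' @param sbr signal-to-background concentration ratio (> 1).
#' @param acq an [acquisition_spec()]; `matrix_size` sets the grid.
#' @param recon_cfg a [recon_config()].
#' @param bg_MBq_per_mL background activity concentration.
#' @return list with `quant` (Bq `image_volume`), `sphere_mask`,
#'   `true_activity_Bq`, `seed_box`, `volume_mL`, `sbr`.
#' @export
simulate_sphere_phantom <- function(volume_mL, sbr, acq,
                                    recon_cfg = recon_config(broad_beam_scale = 1),
                                    bg_MBq_per_mL = 0.002) {
  stopifnot(volume_mL > 0, sbr > 1)
  n <- acq$matrix_size
  sp <- acq$pixel_mm
  r_mm <- (3 * volume_mL * 1000 / (4 * pi))^(1 / 3)
  template <- image_volume(array(0, c(n, n, n)), sp)
  ctr <- voxel_centres(template)
  # keep the background shell well inside the body but the body clear of
  # the grid edge
  body_r <- min(n * sp / 2 * 0.95, r_mm + 55)
  bq <- outer(ctr[[1]]^2, ctr[[2]]^2, `+`)
  body <- outer(bq, rep(0, n), `+`) <= body_r^2
  rq <- outer(ctr[[1]]^2, ctr[[2]]^2, `+`)
  sphere <- outer(rq, ctr[[3]]^2, `+`) <= r_mm^2
  voxvol <- voxel_volume_ml(template)
  act <- array(0, c(n, n, n))
  act[body] <- bg_MBq_per_mL * voxvol
  act[sphere] <- sbr * bg_MBq_per_mL * voxvol
  act_vol <- vol_like(act * 1e6, template, "Bq")
  mu <- array(0, c(n, n, n))
  mu[body] <- mu_water_140kev()
  mu_vol <- vol_like(mu, template, "cm^-1")
  proj <- simulate_spect(act_vol, mu_vol, acq)
  recon <- osem_reconstruct(proj, mu_vol, recon_cfg)
  cf <- calibrate(1, 1, 1, 1 / acq$sensitivity_cps_per_MBq)  # ideal factor
  quant <- counts_to_activity(recon, cf,
                              acq$n_projections * acq$seconds_per_projection)
  idx <- which(sphere, arr.ind = TRUE)
  pad <- max(3L, ceiling(22 / sp))
  seed_box <- list(lo = pmax(1L, apply(idx, 2, min) - pad),
                   hi = pmin(n, apply(idx, 2, max) + pad))
  list(quant = quant, sphere_mask = sphere, body_mask = body,
       true_activity_Bq = sbr * bg_MBq_per_mL * voxvol * sum(sphere) * 1e6,
       seed_box = seed_box, volume_mL = sum(sphere) * voxvol, sbr = sbr)
}

# binary dilation of a 3-D mask by (euclidean) radius r voxels
dilate3d <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  d <- dim(mask)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dx^2 + dy^2 + dz^2 > r^2 + 1e-9) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] | mask[xs - dx, ys - dy, zs - dz]
  }
  out
}

box_mask <- function(dims, box) {
  m <- array(FALSE, dims)
  m[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- TRUE
  m
}

# 2-voxel-thick background rind at a 2-voxel gap around a seed box
background_shell <- function(dims, box, gap = 2L, width = 2L) {
  inner <- list(lo = pmax(1L, box$lo - gap), hi = pmin(dims, box$hi + gap))
  outer_ <- list(lo = pmax(1L, box$lo - gap - width),
                 hi = pmin(dims, box$hi + gap + width))
  box_mask(dims, outer_) & !box_mask(dims, inner)
}

# threshold (percent of box max) whose mask matches a target via bisection;
# target_fun(mask_values, n) -> recovered quantity, decreasing in threshold
bisect_threshold <- function(vals_in_box, target, recover,
                             lo = 0.5, hi = 99.5, tol = 0.01) {
  f <- function(Tpct) recover(Tpct) - target
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo < 0 || fhi > 0) return(NA_real_)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm >= 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Optimal volume/activity thresholds for one calibration cell
#'
#' Finds, by bisection on the threshold (percent of the maximum inside the
#' seed box), the threshold whose mask volume equals the true volume, and
#' the threshold at which the background-subtracted mask activity equals
#' the object's true excess activity (total activity minus the background
#' concentration over the true volume). Background subtraction makes the
#' estimator recover the hot object's excess over its surroundings; the
#' background contribution over the object volume is restored explicitly
#' when total activity is reported (see [segment_region()]).
#'
#' @param cell a [simulate_sphere_phantom()] result.
#' @return list with `T_vol`, `T_act` (percent, `NA` when non-bracketing)
#'   and the observed `sbr`.
#' @export
optimal_thresholds <- function(cell) {
  q <- unclass(cell$quant)
  dims <- dim(q)
  inbox <- box_mask(dims, cell$seed_box)
  vals <- q[inbox]
  mx <- max(vals)
  shell <- background_shell(dims, cell$seed_box)
  if (!is.null(cell$body_mask)) shell <- shell & cell$body_mask
  bg <- mean(q[shell])
  sbr_obs <- mx / bg
  voxvol <- voxel_volume_ml(cell$quant)
  T_vol <- bisect_threshold(vals, cell$volume_mL, function(Tpct)
    sum(vals >= Tpct / 100 * mx) * voxvol)
  excess_true <- cell$true_activity_Bq - bg * cell$volume_mL / voxvol
  T_act <- bisect_threshold(vals, excess_true, function(Tpct) {
    m <- vals >= Tpct / 100 * mx
    sum(vals[m]) - bg * sum(m)
  })
  list(T_vol = T_vol, T_act = T_act, sbr = sbr_obs)
}

#' Build the two calibration curves from a sphere phantom grid
#'
#' Simulates every (volume, SBR) cell, finds the optimal thresholds, and
#' fits `T(SBR) = a + b/SBR` for the volume and activity curves by least
#' squares. Cells where the bisection does not bracket are dropped with a
#' warning; fewer than 4 valid cells is an error.
#'
#' @param sphere_volumes_mL sphere volumes (all >= 12 mL).
#' @param sbr_levels signal-to-background ratios (> 1).
#' @param acq an [acquisition_spec()].
#' @param recon_cfg a [recon_config()].
#' @param cells optional precomputed list of [simulate_sphere_phantom()]
#'   results (overrides the volume/SBR grid).
#' @return list with `volume` and `activity` curves (`a`, `b`, `sbr_range`,
#'   `volumes_used`) plus the per-cell `table`.
#' @export
build_calibration_curves <- function(sphere_volumes_mL = c(12, 30, 100),
                                     sbr_levels = c(2, 8, 32),
                                     acq = acquisition_spec(matrix_size = 48,
                                                            poisson = FALSE),
                                     recon_cfg = recon_config(broad_beam_scale = 1),
                                     cells = NULL) {
  if (is.null(cells)) {
    stopifnot(all(sphere_volumes_mL >= 12), all(sbr_levels > 1))
    grid <- expand.grid(volume_mL = sphere_volumes_mL, sbr = sbr_levels)
    cells <- lapply(seq_len(nrow(grid)), function(i)
      simulate_sphere_phantom(grid$volume_mL[i], grid$sbr[i], acq, recon_cfg))
  }
  rows <- lapply(cells, function(cell) {
    th <- optimal_thresholds(cell)
    data.frame(volume_mL = cell$volume_mL, sbr_nominal = cell$sbr,
               sbr = th$sbr, T_vol = th$T_vol, T_act = th$T_act)
  })
  tab <- do.call(rbind, rows)
  bad <- is.na(tab$T_vol) | is.na(tab$T_act)
  if (any(bad)) {
    warning(sum(bad), " calibration cell(s) dropped (non-bracketing)")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (nrow(tab) < 4) stop("fewer than 4 valid calibration cells")
  fit_curve <- function(Tcol, kind) {
    f <- stats::lm(tab[[Tcol]] ~ I(1 / tab$sbr))
    structure(list(kind = kind, a = unname(stats::coef(f)[1]),
                   b = unname(stats::coef(f)[2]),
                   sbr_range = range(tab$sbr),
                   volumes_used = sort(unique(tab$volume_mL))),
              class = "calibration_curve")
  }
  list(volume = fit_curve("T_vol", "volume"),
       activity = fit_curve("T_act", "activity"),
       table = tab)
}

#' Evaluate a calibration curve at an SBR
#' @param curve a `calibration_curve`.
#' @param sbr signal-to-background ratio (may be `Inf`: the intercept).
#' @export
curve_threshold <- function(curve, sbr) {
  Tpct <- curve$a + curve$b / sbr
  min(max(Tpct, 0.5), 99.5)
}

#' Save / load calibration curves as JSON
#' @param curves result of [build_calibration_curves()].
#' @param path JSON file path.
#' @export
write_calibration_curves <- function(curves, path) {
  jsonlite::write_json(lapply(curves[c("volume", "activity")], unclass),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_curves
#' @export
read_calibration_curves <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) structure(x, class = "calibration_curve"))
}

#' Segment one region of a quantitative SPECT volume
#'
#' Dual iterative adaptive thresholding: the signal-to-background ratio is
#' the ratio of the maximum voxel in the current mask to the mean of a
#' background shell around the seed box; the volume (resp. activity)
#' calibration curve turns the SBR into a threshold, expressed as percent
#' of the regional maximum; thresholding is iterated until the mask volume
#' changes by less than 1% (or 20 iterations, or an oscillation is
#' detected). The reported activity is the background-subtracted sum over
#' the activity mask (the object's excess over its surroundings, which is
#' what the activity curve is calibrated to recover) plus the background
#' concentration restored over the measured object volume, giving total
#' object activity.
#'
#' @param quant_volume activity `image_volume` (Bq).
#' @param seed_box list with `lo` and `hi` voxel index triplets bracketing
#'   the object (must contain its maximum).
#' @param curves calibration curves from [build_calibration_curves()].
#' @param label region label carried through to the result.
#' @param exclude optional logical array of voxels to exclude from both
#'   the seed box and the background shell (e.g. neighbouring organs).
#' @param support optional logical array restricting the background shell
#'   to tissue (e.g. the body mask); keeps out-of-body air from biasing
#'   the background estimate.
#' @return A `segmentation_result`: list with `label`, `volume_mask`,
#'   `activity_mask`, `sbr`, `T_vol`, `T_act`, `volume_mL`, `activity_Bq`,
#'   `iterations`, `converged`.
#' @export
segment_region <- function(quant_volume, seed_box, curves, label = "region",
                           exclude = NULL, support = NULL) {
  q <- unclass(quant_volume)
  dims <- dim(q)
  inbox <- box_mask(dims, seed_box)
  shell <- background_shell(dims, seed_box)
  if (!is.null(exclude)) {
    inbox <- inbox & !exclude
    shell <- shell & !exclude
  }
  if (!is.null(support)) shell <- shell & support
  if (!any(shell)) stop("empty background shell")
  bg <- mean(q[shell])
  run <- function(curve) {
    mask <- inbox
    prev_n <- sum(mask)
    seen <- integer(0)
    converged <- FALSE
    iters <- 0L
    sbr <- NA_real_
    Tpct <- NA_real_
    for (i in 1:20) {
      iters <- i
      mx <- max(q[mask])
      sbr <- if (bg > 0) mx / bg else Inf
      if (sbr <= 1) stop("object indistinct from background (SBR <= 1)")
      Tpct <- curve_threshold(curve, sbr)
      mask <- inbox & (q >= Tpct / 100 * mx)
      n <- sum(mask)
      if (n == 0) stop("threshold removed the whole object")
      if (abs(n - prev_n) / prev_n < 0.01) { converged <- TRUE; break }
      if (n %in% seen) break  # oscillation: keep last iterate
      seen <- c(seen, prev_n)
      prev_n <- n
    }
    list(mask = mask, sbr = sbr, Tpct = Tpct, iterations = iters,
         converged = converged)
  }
  v <- run(curves$volume)
  a <- run(curves$activity)
  voxvol <- voxel_volume_ml(quant_volume)
  excess <- max(0, sum(q[a$mask]) - bg * sum(a$mask))
  structure(list(label = label, volume_mask = v$mask,
                 activity_mask = a$mask, sbr = v$sbr,
                 T_vol = v$Tpct, T_act = a$Tpct,
                 volume_mL = sum(v$mask) * voxvol,
                 activity_Bq = excess + bg * sum(v$mask),
                 iterations = max(v$iterations, a$iterations),
                 converged = v$converged && a$converged),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %s: %.1f mL, %.4g Bq (SBR %.2f, T_vol %.1f%%, T_act %.1f%%)%s\n",
    x$label, x$volume_mL, x$activity_Bq, x$sbr, x$T_vol, x$T_act,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}
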