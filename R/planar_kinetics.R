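#' Half-maximum ROI on a planar image
#'
#' Starting from an oversized, manually drawn region, keeps the pixels whose
#' counts are at least 50% of the regional maximum (inclusive threshold, so
#' ties at exactly half-maximum are kept). This ROI50 tracks the organ core
#' and is robust to the exact outline of the oversized region.
#'
#' @param img a [planar_image()].
#' @param oversized_mask logical matrix on the same grid.
#' @param label region label carried through to the result.
#' @param threshold_frac threshold as a fraction of the regional maximum.
#' @return An `roi2d`: list with `label`, `mask`, `background` (initially
#'   `NULL`), `source`.
#' @export
make_roi50 <- function(img, oversized_mask, label = "region",
                       threshold_frac = 0.5) {
  stopifnot(identical(dim(img), dim(oversized_mask)), any(oversized_mask))
  mx <- max(img[oversized_mask])
  if (mx <= 0) stop("no signal inside the oversized ROI for '", label, "'")
  mask <- oversized_mask & (unclass(img) >= threshold_frac * mx)
  structure(list(label = label, mask = mask, background = NULL,
                 source = "threshold50"), class = "roi2d")
}

#' Attach a background mask to an ROI
#' @param roi an `roi2d`.
#' @param background logical matrix, disjoint from the ROI mask.
#' @export
set_roi_background <- function(roi, background) {
  stopifnot(identical(dim(background), dim(roi$mask)))
  if (any(background & roi$mask)) stop("background overlaps the ROI")
  if (!any(background)) stop("empty background mask")
  roi$background <- background
  roi
}

# integer-shift normalized cross-correlation between a template patch of
# `ref` (bounding box of `mask` + margin) and `img`
ncc_shift <- function(ref, img, mask, max_shift = 10, margin = 4) {
  idx <- which(mask, arr.ind = TRUE)
  r1 <- max(1, min(idx[, 1]) - margin); r2 <- min(nrow(ref), max(idx[, 1]) + margin)
  c1 <- max(1, min(idx[, 2]) - margin); c2 <- min(ncol(ref), max(idx[, 2]) + margin)
  tpl <- unclass(ref)[r1:r2, c1:c2]
  tpl <- tpl - mean(tpl)
  tn <- sqrt(sum(tpl^2))
  best <- c(0, 0); best_ncc <- -Inf
  im <- unclass(img)
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    rr <- (r1 + dx):(r2 + dx); cc <- (c1 + dy):(c2 + dy)
    if (min(rr) < 1 || max(rr) > nrow(im) || min(cc) < 1 || max(cc) > ncol(im))
      next
    w <- im[rr, cc]
    w <- w - mean(w)
    den <- tn * sqrt(sum(w^2))
    ncc <- if (den > 0) sum(tpl * w) / den else -Inf
    if (ncc > best_ncc) { best_ncc <- ncc; best <- c(dx, dy) }
  }
  list(shift = best, ncc = best_ncc,
       at_edge = any(abs(best) == max_shift))
}

shift_mask <- function(mask, shift) {
  out <- array(FALSE, dim(mask))
  idx <- which(mask, arr.ind = TRUE)
  idx[, 1] <- idx[, 1] + shift[1]
  idx[, 2] <- idx[, 2] + shift[2]
  ok <- idx[, 1] >= 1 & idx[, 1] <= nrow(mask) &
    idx[, 2] >= 1 & idx[, 2] <= ncol(mask)
  out[idx[ok, , drop = FALSE]] <- TRUE
  out
}

#' Propagate an ROI across a planar time series
#'
#' Registers the ROI neighbourhood of the reference image to every image in
#' the series by maximizing normalized cross-correlation over integer
#' translations inside a bounded window, then translates ROI and background
#' masks accordingly. NCC is invariant to global intensity scale, so decay
#' between time points does not bias the shift.
#'
#' @param roi an `roi2d` defined on the first image of `series`.
#' @param series list of [planar_image()]s on a common pixel grid.
#' @param max_shift search window half-width in pixels.
#' @return list of `roi2d`, one per time point, each with a `shift` and an
#'   `at_edge` warning flag.
#' @export
propagate_roi <- function(roi, series, max_shift = 10) {
  ref <- series[[1]]
  lapply(series, function(img) {
    if (!isTRUE(all.equal(attr(img, "spacing"), attr(ref, "spacing"))))
      stop("planar series must share a pixel grid; resample first")
    sh <- ncc_shift(ref, img, roi$mask, max_shift)
    out <- roi
    out$mask <- shift_mask(roi$mask, sh$shift)
    if (!is.null(roi$background))
      out$background <- shift_mask(roi$background, sh$shift)
    out$shift <- sh$shift
    out$at_edge <- sh$at_edge
    out
  })
}

#' Background-corrected ROI counts
#'
#' `sum(counts in ROI) - mean(background per pixel) * n_ROI_pixels`,
#' floored at zero (with a flag) if the subtraction overshoots.
#'
#' @param img a [planar_image()].
#' @param roi an `roi2d` with a background mask.
#' @return list with `corrected`, `raw`, `background_per_px`, `clipped`.
#' @export
background_corrected_counts <- function(img, roi) {
  if (is.null(roi$background) || !any(roi$background))
    stop("ROI has no background mask")
  raw <- sum(img[roi$mask])
  bg <- mean(img[roi$background])
  corrected <- raw - bg * sum(roi$mask)
  clipped <- corrected < 0
  list(corrected = max(corrected, 0), raw = raw,
       background_per_px = bg, clipped = clipped)
}

#' Build a time-activity curve for one ROI over a planar series
#'
#' @param series list of planar images (anterior view by default).
#' @param rois per-time ROIs from [propagate_roi()].
#' @param times_h acquisition times (h); defaults to the images' time
#'   stamps.
#' @return data.frame with columns `t_h`, `counts`, `raw`, `bg_per_px`.
#' @export
extract_tac <- function(series, rois, times_h = NULL) {
  times_h <- times_h %||% vapply(series, function(x) attr(x, "time_h"), 0)
  if (is.unsorted(times_h, strictly = TRUE))
    stop("TAC times must be strictly increasing")
  rows <- Map(function(img, roi) {
    b <- background_corrected_counts(img, roi)
    data.frame(counts = b$corrected, raw = b$raw, bg_per_px = b$background_per_px)
  }, series, rois)
  cbind(data.frame(t_h = times_h), do.call(rbind, rows))
}

#' Mono-exponential fit of a time-activity curve
#'
#' Fits `A(t) = A0 * 2^(-t / T_eff)` by least squares on log-counts (exact
#' two-point solution when only two usable samples exist), and derives the
#' biological half-life from `1/T_bio = 1/T_eff - 1/T_phys`. An effective
#' half-life above the physical half-life means net biological accumulation
#' during the observation window: `T_bio` then comes out negative and the
#' fit is flagged, matching how such organs (typically spleen) are reported.
#'
#' @param tac data.frame with columns `t_h` and `counts` (see
#'   [extract_tac()]).
#' @param nuclide a [nuclide_data()]; supplies the physical half-life.
#' @return A `kinetic_fit`: list with `A0`, `T_eff_h`, `lambda_eff`,
#'   `T_bio_h` (`Inf` when T_eff equals T_phys to within 1e-9 relative),
#'   `rss_log` and `flags`.
#' @export
fit_monoexponential <- function(tac, nuclide = nuclide_tc99m()) {
  use <- tac$counts > 0
  if (any(!use))
    warning(sum(!use), " nonpositive TAC point(s) excluded from fit")
  tac <- tac[use, , drop = FALSE]
  if (nrow(tac) < 2) stop("need at least 2 positive-count TAC points")
  flags <- character(0)
  if (nrow(tac) == 2) {
    lambda <- diff(log(tac$counts)) / diff(tac$t_h) * -1
    a0_log <- log(tac$counts[1]) + lambda * tac$t_h[1]
    rss <- 0
  } else {
    f <- stats::lm(log(counts) ~ t_h, data = tac)
    lambda <- -stats::coef(f)[["t_h"]]
    a0_log <- stats::coef(f)[["(Intercept)"]]
    rss <- sum(stats::residuals(f)^2)
  }
  if (lambda <= 0) stop("TAC shows no net washout; cannot fit T_eff > 0")
  T_eff <- LN2 / lambda
  T_phys <- nuclide$half_life_h
  T_bio <- if (abs(T_eff - T_phys) < 1e-9 * T_phys) Inf
  else T_eff * T_phys / (T_phys - T_eff)
  if (is.finite(T_bio) && T_bio < 0) flags <- c(flags, "accumulation")
  structure(list(A0 = exp(a0_log), T_eff_h = T_eff, lambda_eff = lambda,
                 T_bio_h = T_bio, rss_log = rss, flags = flags),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> A0 = %.4g, T_eff = %.4g h, T_bio = %.4g h%s\n",
              x$A0, x$T_eff_h, x$T_bio_h,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Biological half-life from effective and physical half-lives
#'
#' `1/T_bio = 1/T_eff - 1/T_phys`; negative when `T_eff > T_phys`
#' (accumulating organ), `Inf` at equality.
#' @param T_eff_h effective half-life (h).
#' @param T_phys_h physical half-life (h).
#' @export
biological_half_life <- function(T_eff_h, T_phys_h = TC99M_HALF_LIFE_H) {
  ifelse(abs(T_eff_h - T_phys_h) < 1e-9 * T_phys_h, Inf,
         T_eff_h * T_phys_h / (T_phys_h - T_eff_h))
}

# ---- geometric helpers for automated ROI placement ----------------------

dilate2d <- function(mask, r) {
  if (r <= 0) return(mask)
  out <- mask
  for (dx in -r:r) for (dy in -r:r) {
    if (dx == 0 && dy == 0) next
    if (dx^2 + dy^2 > r^2 + 1e-9) next
    nr <- nrow(mask); nc <- ncol(mask)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    xt <- xs - dx
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    yt <- ys - dy
    out[xs, ys] <- out[xs, ys] | mask[xt, yt]
  }
  out
}

#' Automatically placed planar ROIs for phantom studies
#'
#' Emulates the manual step of the protocol: for each phantom region an
#' oversized ROI is the dilated projection of the region's true mask onto
#' the planar grid, with the (dilated) projections of all other regions
#' carved out -- as an operator would steer a VOI clear of neighbouring hot
#' structures -- and the background ROI is an adjacent rind around it,
#' excluding every organ's projection. Intended for synthetic studies where
#' the anatomy is known.
#'
#' @param phantom a [build_phantom()] result.
#' @param regions region names; defaults to all explicit regions.
#' @param margin_px dilation radius of the oversized ROI.
#' @param bg_gap_px,bg_width_px geometry of the background rind.
#' @return named list of `list(oversized, background)` logical matrices on
#'   the planar (x, z) grid.
#' @export
auto_planar_rois <- function(phantom, regions = phantom_regions(phantom),
                             margin_px = 3, bg_gap_px = 2, bg_width_px = 3) {
  all_proj <- array(FALSE, dim(phantom$labels)[c(1, 3)])
  proj <- list()
  for (nm in phantom_regions(phantom)) {
    p <- apply(phantom_mask(phantom, nm), c(1, 3), any)
    proj[[nm]] <- p
    all_proj <- all_proj | p
  }
  body_proj <- apply(phantom_mask(phantom, "body"), c(1, 3), any)
  out <- lapply(regions, function(nm) {
    over <- dilate2d(proj[[nm]], margin_px)
    for (o in setdiff(names(proj), nm))
      over <- over & !dilate2d(proj[[o]], bg_gap_px)
    if (!any(over)) stop("region '", nm, "' fully occluded on the planar view")
    inner <- dilate2d(over, bg_gap_px)
    rind <- dilate2d(inner, bg_width_px) & !inner
    bg <- rind & body_proj & !dilate2d(all_proj, bg_gap_px)
    if (!any(bg)) bg <- rind & body_proj & !all_proj
    list(oversized = over, background = bg)
  })
  names(out) <- regions
  out
}
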