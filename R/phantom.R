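#' Digital phantom specification
#'
#' Describes a torso-like digital phantom: an elliptical-cylinder body and a
#' set of ellipsoidal regions (organs, tumours, bladder). All linear
#' dimensions are multiplied by `age_scale`, so one geometry serves a range
#' of body sizes.
#'
#' @param body list with `half_axes_mm` (length 2: left-right and
#'   anterior-posterior half-axes of the body ellipse).
#' @param regions named list; each element has `center_mm` (length 3),
#'   `half_axes_mm` (length 3) and `density` (g/mL). A region may instead
#'   contain `components`, a list of such ellipsoids, to model a
#'   union-of-ellipsoids shape.
#' @param grid list with `n` (dimensions, length 1 or 3) and `spacing_mm`.
#' @param age_scale scalar multiplying all linear dimensions of body and
#'   regions (not the grid).
#' @param body_mass_g total patient body mass (g); used to apportion
#'   remainder-of-body activity between the in-grid torso and the rest of
#'   the body.
#' @param body_density density of non-organ body tissue (g/mL).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(body, regions, grid, age_scale = 1,
                         body_mass_g = NULL, body_density = 1.0) {
  if (length(grid$n) == 1L) grid$n <- rep(as.integer(grid$n), 3L)
  stopifnot(age_scale > 0, length(body$half_axes_mm) == 2L,
            all(grid$n >= 8L), grid$spacing_mm > 0,
            length(regions) >= 1L, !is.null(names(regions)),
            !anyDuplicated(names(regions)))
  for (r in regions) {
    comps <- r$components %||% list(r)
    for (cc in comps)
      stopifnot(length(cc$center_mm) == 3L, length(cc$half_axes_mm) == 3L,
                all(cc$half_axes_mm > 0))
    stopifnot((r$density %||% 1.0) > 0)
  }
  structure(list(body = body, regions = regions, grid = grid,
                 age_scale = age_scale, body_mass_g = body_mass_g,
                 body_density = body_density),
            class = "phantom_spec")
}

#' Default pediatric phantom (approximately a 12-year-old torso)
#'
#' Organ sizes follow reference pediatric anatomy: paired kidneys about
#' 210 g, liver about 1050 g, spleen about 105 g, torso within a
#' 26 x 18 cm body ellipse, total body mass 40 kg. `age_scale` rescales all
#' linear dimensions (1.2 gives adult-like organ masses).
#'
#' @param age_scale linear scale factor (1 = the ~12-year-old reference).
#' @param grid_n grid dimension (cubic grid).
#' @param spacing_mm voxel size, default the SPECT matrix pixel 4.418 mm.
#' @param tumor include a 30 mL spherical abdominal tumour.
#' @param bladder include a urinary-bladder region.
#' @param body_mass_g total body mass in g.
#' @export
pediatric_phantom_spec <- function(age_scale = 1, grid_n = 96,
                                   spacing_mm = 4.418, tumor = FALSE,
                                   bladder = FALSE, body_mass_g = 40000) {
  regions <- list(
    left_kidney = list(center_mm = c(-55, 30, -60),
                       half_axes_mm = c(26, 18, 53), density = 1.05),
    right_kidney = list(center_mm = c(55, 30, -60),
                        half_axes_mm = c(26, 18, 53), density = 1.05),
    liver = list(center_mm = c(40, -10, 70),
                 half_axes_mm = c(85, 50, 56), density = 1.06),
    spleen = list(center_mm = c(-80, 15, 65),
                  half_axes_mm = c(30, 22, 36), density = 1.06))
  if (tumor)
    regions$tumor_1 <- list(center_mm = c(-5, -40, -50),
                            half_axes_mm = c(19.3, 19.3, 19.3),
                            density = 1.05)
  if (bladder)
    regions$bladder <- list(center_mm = c(0, -20, -140),
                            half_axes_mm = c(30, 30, 30), density = 1.0)
  phantom_spec(body = list(half_axes_mm = c(130, 90)),
               regions = regions,
               grid = list(n = grid_n, spacing_mm = spacing_mm),
               age_scale = age_scale, body_mass_g = body_mass_g)
}

#' Adult-scale phantom
#'
#' The pediatric geometry scaled by 1.2 in all linear dimensions, giving
#' adult-like organ masses (kidneys ~360 g, liver ~1830 g, spleen ~180 g)
#' and a 73 kg body mass.
#' @inheritParams pediatric_phantom_spec
#' @export
adult_phantom_spec <- function(grid_n = 128, spacing_mm = 4.418,
                               tumor = FALSE, bladder = FALSE,
                               body_mass_g = 73000) {
  pediatric_phantom_spec(age_scale = 1.2, grid_n = grid_n,
                         spacing_mm = spacing_mm, tumor = tumor,
                         bladder = bladder, body_mass_g = body_mass_g)
}

region_mask <- function(spec, region, centres) {
  comps <- region$components %||% list(region)
  d <- lengths(centres)
  m <- array(FALSE, d)
  s <- spec$age_scale
  for (cc in comps) {
    dx <- (centres[[1]] - cc$center_mm[1] * s) / (cc$half_axes_mm[1] * s)
    dy <- (centres[[2]] - cc$center_mm[2] * s) / (cc$half_axes_mm[2] * s)
    dz <- (centres[[3]] - cc$center_mm[3] * s) / (cc$half_axes_mm[3] * s)
    q <- outer(dx^2, dy^2, `+`)
    m <- m | (outer(q, dz^2, `+`) <= 1)
  }
  m
}

#' Build a voxelised phantom
#'
#' Rasterises a [phantom_spec()] onto its grid, producing an integer label
#' volume, an attenuation map at 140 keV (water-equivalent, scaled by tissue
#' density, zero outside the body), and a mass table.
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom` object: list with `labels` (integer `image_volume`,
#'   0 = outside body, 1 = body/remainder, 2+ = regions), `label_table`
#'   (data.frame mapping label ids to names), `mu` (attenuation map, cm^-1),
#'   `masses` (data.frame: region, n_voxels, volume_mL, mass_g) including a
#'   `remainder` row (in-grid body minus organs), and the originating `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid$n; sp <- spec$grid$spacing_mm
  template <- image_volume(array(0, n), spacing = sp, units = "label")
  centres <- voxel_centres(template)
  s <- spec$age_scale
  ax <- spec$body$half_axes_mm * s
  bq <- outer((centres[[1]] / ax[1])^2, (centres[[2]] / ax[2])^2, `+`)
  body <- outer(bq, rep(0, n[3]), `+`) <= 1
  labels <- array(0L, n)
  labels[body] <- 1L
  region_names <- names(spec$regions)
  masks <- vector("list", length(region_names))
  names(masks) <- region_names
  for (i in seq_along(region_names)) {
    rn <- region_names[i]
    m <- region_mask(spec, spec$regions[[rn]], centres)
    if (!any(m)) stop("region '", rn, "' rasterises to zero voxels")
    if (any(m & !body))
      stop("region '", rn, "' extends outside the body")
    prev <- labels[m]
    clash <- prev > 1L
    if (any(clash))
      stop("overlapping regions: '", rn, "' and '",
           region_names[max(prev[clash]) - 1L], "'")
    labels[m] <- i + 1L
    masks[[i]] <- m
  }
  voxvol <- prod(rep(sp, length.out = 3)) / 1000  # mL
  dens <- vapply(spec$regions, function(r) r$density %||% 1.0, 0)
  n_vox <- vapply(masks, sum, 0L)
  remainder_n <- sum(labels == 1L)
  masses <- data.frame(
    region = c(region_names, "remainder"),
    n_voxels = c(n_vox, remainder_n),
    volume_mL = c(n_vox, remainder_n) * voxvol,
    mass_g = c(n_vox * voxvol * dens,
               remainder_n * voxvol * spec$body_density),
    row.names = NULL)
  mu140 <- mu_water_140kev()
  mu <- array(0, n)
  mu[labels == 1L] <- mu140 * spec$body_density
  for (i in seq_along(region_names))
    mu[masks[[i]]] <- mu140 * dens[i]
  structure(list(
    labels = vol_like(labels, template, "label"),
    label_table = data.frame(label = c(1L, seq_along(region_names) + 1L),
                             region = c("remainder", region_names)),
    mu = vol_like(mu, template, "cm^-1"),
    masses = masses,
    spec = spec), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom>\n")
  print(x$masses, row.names = FALSE)
  invisible(x)
}

#' Logical mask of a phantom region
#'
#' @param phantom a [build_phantom()] result.
#' @param region region name, `"remainder"` (in-grid body minus all regions)
#'   or `"body"` (everything inside the body surface).
#' @export
phantom_mask <- function(phantom, region) {
  lt <- phantom$label_table
  lab <- unclass(phantom$labels)
  if (region == "body") return(lab >= 1L)
  if (!region %in% lt$region) stop("unknown region '", region, "'")
  lab == lt$label[match(region, lt$region)]
}

#' Names of the explicit (non-remainder) phantom regions
#' @param phantom a `phantom`.
#' @export
phantom_regions <- function(phantom)
  setdiff(phantom$label_table$region, "remainder")

#' Fraction of total body mass contained in the phantom grid
#'
#' The grid holds a torso; the remainder of the body (head, limbs) lies
#' outside it. When populating the phantom with whole-body remainder
#' activity this fraction apportions the activity to the in-grid tissue.
#' @param phantom a `phantom`.
#' @export
torso_mass_fraction <- function(phantom) {
  if (is.null(phantom$spec$body_mass_g)) return(1)
  min(1, sum(phantom$masses$mass_g) / phantom$spec$body_mass_g)
}
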