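#' Kinetics specification for the phantom simulator
#'
#' Mono-exponential washout per region, with an optional uptake phase:
#' the fraction of injected activity in region r at time t is
#' `f0 * (1 - 2^(-t/T_up)) * 2^(-t/T_eff)` (uptake term omitted when
#' `T_up` is absent). The effective half-life `T_eff` already contains
#' physical decay. Urinary excretion removes activity from the whole body
#' with biological half-life `T_u`; the remainder region carries whatever
#' whole-body activity is not in an explicit region.
#'
#' @param injected_MBq injected activity in MBq.
#' @param regions named list; each element a list with `f0` (fraction of
#'   injected activity extrapolated to t = 0+), `T_eff_h` (> 0) and
#'   optionally `T_up_h`.
#' @param f_u fraction of injected activity excreted to urine.
#' @param T_u_h urinary biological half-life (h).
#' @param nuclide a [nuclide_data()]; defaults to Tc-99m.
#' @export
kinetics_spec <- function(injected_MBq, regions, f_u = 0.5, T_u_h = 2,
                          nuclide = nuclide_tc99m()) {
  stopifnot(injected_MBq > 0, f_u >= 0, f_u <= 1, T_u_h > 0,
            length(regions) >= 1L, !is.null(names(regions)))
  f0 <- vapply(regions, function(r) r$f0, 0)
  te <- vapply(regions, function(r) r$T_eff_h, 0)
  if (any(f0 < 0) || any(te <= 0)) stop("invalid f0 or T_eff in kinetics")
  if (sum(f0) + f_u > 1)
    stop("sum of region f0 plus urinary fraction exceeds 1")
  if (any(te > nuclide$half_life_h))
    warning("region T_eff exceeds the physical half-life (net accumulation)")
  structure(list(injected_MBq = injected_MBq, regions = regions,
                 f_u = f_u, T_u_h = T_u_h, nuclide = nuclide),
            class = "kinetics_spec")
}

#' Default pediatric kinetics
#'
#' Effective half-lives and uptake fractions typical of a Tc-99m
#' somatostatin-analogue study: kidneys ~4.7-4.9 h, liver ~5.1 h,
#' spleen ~5.8 h effective half-life, with organ TIACs around
#' 0.19/0.19/0.56/0.43 h (left kidney/right kidney/liver/spleen) and half the
#' activity excreted in urine.
#'
#' @param injected_MBq injected activity (MBq).
#' @param tumor include a tumour region (TIAC ~0.07 h, T_eff 4.18 h).
#' @export
default_kinetics_spec <- function(injected_MBq = 500, tumor = FALSE) {
  regions <- list(
    left_kidney = list(f0 = 0.185 * LN2 / 4.72, T_eff_h = 4.72),
    right_kidney = list(f0 = 0.185 * LN2 / 4.94, T_eff_h = 4.94),
    liver = list(f0 = 0.56 * LN2 / 5.07, T_eff_h = 5.07),
    spleen = list(f0 = 0.43 * LN2 / 5.83, T_eff_h = 5.83))
  if (tumor)
    regions$tumor_1 <- list(f0 = 0.07 * LN2 / 4.18, T_eff_h = 4.18)
  kinetics_spec(injected_MBq, regions)
}

#' Region activity at time t (MBq)
#' @param kin a [kinetics_spec()].
#' @param region region name.
#' @param t_h hours post-injection (vectorised).
#' @export
region_activity <- function(kin, region, t_h) {
  if (any(t_h < 0)) stop("t must be >= 0")
  r <- kin$regions[[region]]
  if (is.null(r)) stop("no kinetics for region '", region, "'")
  a <- kin$injected_MBq * r$f0 * 2^(-t_h / r$T_eff_h)
  if (!is.null(r$T_up_h)) a <- a * (1 - 2^(-t_h / r$T_up_h))
  a
}

#' Whole-body activity at time t (MBq)
#'
#' Physical decay times urinary retention:
#' `A_inj * 2^(-t/T_phys) * (1 - f_u * (1 - 2^(-t/T_u)))`.
#' @inheritParams region_activity
#' @export
whole_body_activity <- function(kin, t_h) {
  if (any(t_h < 0)) stop("t must be >= 0")
  kin$injected_MBq * 2^(-t_h / kin$nuclide$half_life_h) *
    (1 - kin$f_u * (1 - 2^(-t_h / kin$T_u_h)))
}

#' Ground-truth time-integrated activity coefficients of a kinetics spec
#'
#' Organ TIACs are analytic (`f0 * T_eff / ln 2`, with the closed-form
#' correction when an uptake phase is present); the remainder TIAC is the
#' numerically integrated whole-body minus organ activity. All values are in
#' hours (Bq.h per Bq injected).
#'
#' @param kin a [kinetics_spec()].
#' @param t_max_h upper integration limit for the remainder term; defaults
#'   to ten physical half-lives.
#' @return named numeric vector, including `whole_body` and `remainder`.
#' @export
true_tiacs <- function(kin, t_max_h = 10 * kin$nuclide$half_life_h) {
  organ <- vapply(names(kin$regions), function(nm) {
    r <- kin$regions[[nm]]
    ti <- r$f0 * r$T_eff_h / LN2
    if (!is.null(r$T_up_h))  # subtract the unreached uptake portion
      ti <- ti - r$f0 / (LN2 / r$T_eff_h + LN2 / r$T_up_h)
    ti
  }, 0)
  wb <- stats::integrate(function(t) whole_body_activity(kin, t) /
                           kin$injected_MBq, 0, t_max_h,
                         subdivisions = 2000L)$value
  rem <- wb - sum(organ)
  c(organ, whole_body = wb, remainder = rem)
}

#' Voxelised activity map at time t
#'
#' Every explicit kinetics region must exist in the phantom; activity is
#' uniform within a region. The leftover whole-body activity is
#' distributed over the whole remainder body mass, of which only the
#' in-grid torso fraction ([torso_mass_fraction()]) lands in the grid: the
#' head and limbs lie outside the imaged volume.
#'
#' @param phantom a [build_phantom()] result.
#' @param kin a [kinetics_spec()].
#' @param t_h time post-injection in hours (scalar, >= 0).
#' @return `image_volume` in Bq (total activity per voxel).
#' @export
activity_map <- function(phantom, kin, t_h) {
  if (length(t_h) != 1L || t_h < 0) stop("t must be a scalar >= 0")
  act <- array(0, dim(phantom$labels))
  total_organ <- 0
  for (nm in names(kin$regions)) {
    m <- phantom_mask(phantom, nm)
    a <- region_activity(kin, nm, t_h)
    act[m] <- a / sum(m)
    total_organ <- total_organ + a
  }
  rem_act <- whole_body_activity(kin, t_h) - total_organ
  if (rem_act < -1e-9 * kin$injected_MBq)
    stop("organ activities exceed whole-body activity at t = ", t_h, " h")
  mrem <- phantom_mask(phantom, "remainder")
  act[mrem] <- max(rem_act, 0) * torso_mass_fraction(phantom) / sum(mrem)
  vol_like(act * 1e6, phantom$labels, units = "Bq")
}
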