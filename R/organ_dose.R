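#' Derive an organ-level S-factor table from the voxel kernel
#'
#' `S[target][source]` is the mean dose (mGy) over the target region per
#' 1 MBq.h of cumulated activity distributed uniformly in the source
#' region, computed with the same voxel S-value kernel as the voxel-level
#' arm — so the two dosimetry arms are comparable by construction rather
#' than by reference to external phantom tables. The electron
#' (non-penetrating) and photon (penetrating) components are kept separate
#' for mass adaptation; electron cross terms are exactly zero for disjoint
#' regions.
#'
#' @param phantom a [build_phantom()] result.
#' @param kernel a [build_kernel()] on the phantom's voxel size.
#' @param sources source region names; defaults to all explicit regions
#'   plus `remainder`.
#' @param targets target region names; defaults to the explicit regions.
#' @return An `sfactor_table`: list with matrices `S_electron`, `S_photon`
#'   (target x source, mGy/(MBq.h)) and `m_ref` (named reference masses, g).
#' @export
derive_sfactors <- function(phantom, kernel,
                            sources = c(phantom_regions(phantom), "remainder"),
                            targets = phantom_regions(phantom)) {
  if (!length(targets)) stop("phantom has no organ regions")
  tmasks <- lapply(targets, function(nm) phantom_mask(phantom, nm))
  names(tmasks) <- targets
  S_e <- S_p <- matrix(0, length(targets), length(sources),
                       dimnames = list(targets, sources))
  voxvol <- voxel_volume_ml(phantom$labels)
  for (s in sources) {
    ms <- phantom_mask(phantom, s)
    if (!any(ms)) stop("source region '", s, "' is empty")
    amap <- array(0, dim(phantom$labels))
    amap[ms] <- 1 / sum(ms)  # 1 MBq.h total, uniform
    avol <- vol_like(amap, phantom$labels, "MBq.h")
    dp <- unclass(dose_map(avol, kernel, components = "photon"))
    for (t in targets) {
      mt <- tmasks[[t]]
      S_p[t, s] <- mean(dp[mt])
      # electron dose is local: mean over target of k_e0 * a (same voxel)
      S_e[t, s] <- kernel$k_electron0 * sum(amap[mt]) / sum(mt)
    }
  }
  # the remainder TIAC refers to the whole-body remainder, of which only
  # the in-grid torso fraction irradiates the phantom organs
  if ("remainder" %in% sources) {
    f <- torso_mass_fraction(phantom)
    S_e[, "remainder"] <- S_e[, "remainder"] * f
    S_p[, "remainder"] <- S_p[, "remainder"] * f
  }
  m_ref <- stats::setNames(
    phantom$masses$mass_g[match(targets, phantom$masses$region)], targets)
  structure(list(S_electron = S_e, S_photon = S_p, m_ref = m_ref,
                 voxel_mm = kernel$voxel_mm),
            class = "sfactor_table")
}

#' @export
print.sfactor_table <- function(x, ...) {
  cat("<sfactor_table> S = S_electron + S_photon, mGy/(MBq.h)\n")
  print(signif(x$S_electron + x$S_photon, 4))
  invisible(x)
}

#' Adapt an S-factor table to patient organ masses
#'
#' Standard absorbed-fraction mass scaling for organ self-dose: the
#' electron (non-penetrating) self component scales as `m_ref/m`, the
#' photon self component as `(m_ref/m)^(2/3)`; cross terms are left
#' unchanged.
#'
#' @param table an [derive_sfactors()] result.
#' @param patient_masses_g named vector of patient organ masses (g); every
#'   table target must be present.
#' @return a new `sfactor_table` (with `m_patient` recorded).
#' @export
adapt_masses <- function(table, patient_masses_g) {
  targets <- rownames(table$S_electron)
  missing <- setdiff(targets, names(patient_masses_g))
  if (length(missing))
    stop("missing patient mass for: ", paste(missing, collapse = ", "))
  if (any(patient_masses_g[targets] <= 0)) stop("masses must be positive")
  out <- table
  for (t in targets) {
    ratio <- table$m_ref[[t]] / patient_masses_g[[t]]
    if (t %in% colnames(table$S_electron)) {
      out$S_electron[t, t] <- table$S_electron[t, t] * ratio
      out$S_photon[t, t] <- table$S_photon[t, t] * ratio^(2 / 3)
    }
  }
  out$m_patient <- patient_masses_g[targets]
  out
}

#' Organ doses from TIACs and an S-factor table (MIRD schema)
#'
#' `D_target = sum_source tiac_source * S[target][source]`, reported per
#' unit injected activity (mGy/MBq when TIACs are in hours).
#'
#' @param tiacs_h named TIAC vector (h); every name must be a table source
#'   column (the remainder entry maps to the body-minus-organs source).
#' @param table an `sfactor_table`.
#' @return data.frame with `region` and `dose_mGy_per_MBq`.
#' @export
organ_doses <- function(tiacs_h, table) {
  S <- table$S_electron + table$S_photon
  unmapped <- setdiff(names(tiacs_h), colnames(S))
  if (length(unmapped))
    stop("TIAC source(s) without an S-factor column: ",
         paste(unmapped, collapse = ", "))
  ti <- stats::setNames(rep(0, ncol(S)), colnames(S))
  ti[names(tiacs_h)] <- tiacs_h
  data.frame(region = rownames(S),
             dose_mGy_per_MBq = as.numeric(S %*% ti),
             row.names = NULL)
}

# pair-distance density of a uniform sphere of radius R: p(s), s in [0, 2R]
sphere_pair_density <- function(s, R) {
  3 * s^2 / R^3 * (1 - 3 * s / (4 * R) + s^3 / (16 * R^3))
}

#' Self-dose of a uniform unit-density sphere (tumour sphere model)
#'
#' Electron energy is absorbed locally (`Delta_e * tiac / m`); the photon
#' self-dose averages the analytic point kernel over the sphere's
#' pair-distance distribution. Cross-organ dose is excluded by
#' construction, mirroring how sphere-model tumour doses omit dose from
#' surrounding organs.
#'
#' @param tumor_mass_g sphere mass (g), within 1-1000 g.
#' @param tiac_h tumour TIAC (h per unit injected activity).
#' @param nuclide a [nuclide_data()].
#' @param density sphere density (g/mL).
#' @return dose in mGy per MBq injected.
#' @export
sphere_dose <- function(tumor_mass_g, tiac_h, nuclide = nuclide_tc99m(),
                        density = 1.0) {
  if (tumor_mass_g < 1 || tumor_mass_g > 1000)
    stop("tumour mass outside the tabulated 1-1000 g range")
  stopifnot(tiac_h >= 0)
  R <- (3 * tumor_mass_g / density / (4 * pi))^(1 / 3)  # cm
  lines <- photon_lines(nuclide, density)
  integrand <- function(s) sphere_pair_density(s, R) *
    photon_point_kernel(s, lines)
  photon <- stats::integrate(integrand, 0, 2 * R, subdivisions = 500L,
                             rel.tol = 1e-8)$value
  electron <- electron_energy_j_per_mbqh(nuclide) /
    (tumor_mass_g / 1000) * 1000  # mGy per MBq.h
  tiac_h * (electron + photon)
}
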