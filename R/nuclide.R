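#' Nuclide decay data
#'
#' Physical half-life plus a per-decay emission table (photons and electrons,
#' energy in keV, yield per decay). The default constructor loads the Tc-99m
#' table packaged under `extdata`; emission constants are standard
#' nuclear-data compilation values, never invented in code.
#'
#' @param half_life_h physical half-life in hours.
#' @param emissions data.frame with columns `type` ("photon"/"electron"),
#'   `energy_keV`, `yield`.
#' @export
nuclide_data <- function(half_life_h, emissions) {
  stopifnot(half_life_h > 0,
            all(c("type", "energy_keV", "yield") %in% names(emissions)),
            all(emissions$yield >= 0), all(emissions$energy_keV > 0),
            all(emissions$type %in% c("photon", "electron")))
  structure(list(half_life_h = half_life_h,
                 emissions = emissions[c("type", "energy_keV", "yield")]),
            class = "nuclide_data")
}

#' @rdname nuclide_data
#' @export
nuclide_tc99m <- function() {
  cache_get("nuclide_tc99m", function() {
    path <- system.file("extdata", "tc99m_emissions.csv",
                        package = "hybridose", mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#")
    nuclide_data(TC99M_HALF_LIFE_H, tab)
  })
}

#' @export
print.nuclide_data <- function(x, ...) {
  cat(sprintf("<nuclide_data> T_phys = %.4f h, %d emission lines\n",
              x$half_life_h, nrow(x$emissions)))
  invisible(x)
}

#' Mean energy emitted per decay (MeV)
#' @param nuclide a [nuclide_data()] object.
#' @param type `"photon"`, `"electron"` or `"all"`.
#' @export
energy_per_decay_mev <- function(nuclide, type = "all") {
  em <- nuclide$emissions
  if (type != "all") em <- em[em$type == type, ]
  sum(em$energy_keV * em$yield) / 1000
}

# ---- water photon coefficients ------------------------------------------

water_coefficient_table <- function() {
  cache_get("water_coeffs", function() {
    path <- system.file("extdata", "water_photon_coefficients.csv",
                        package = "hybridose", mustWork = TRUE)
    utils::read.csv(path, comment.char = "#")
  })
}

# log-log interpolation of a tabulated coefficient column at energy keV
interp_coeff <- function(energy_keV, column) {
  tab <- water_coefficient_table()
  if (any(energy_keV < min(tab$energy_keV) | energy_keV > max(tab$energy_keV)))
    stop("photon energy outside packaged coefficient table (",
         min(tab$energy_keV), "-", max(tab$energy_keV), " keV)")
  exp(stats::approx(log(tab$energy_keV), log(tab[[column]]),
                    xout = log(energy_keV))$y)
}

#' Water photon coefficients at given energies
#'
#' Log-log interpolation of the packaged compilation table.
#'
#' @param energy_keV photon energies in keV.
#' @return data.frame with `mu_rho` (mass attenuation, cm^2/g),
#'   `mu_en_rho` (mass energy-absorption, cm^2/g) and `buildup_a`
#'   (linear-buildup coefficient); linear coefficients for unit-density water
#'   are numerically equal to the mass coefficients.
#' @export
water_photon_coefficients <- function(energy_keV) {
  data.frame(energy_keV = energy_keV,
             mu_rho = interp_coeff(energy_keV, "mu_rho_cm2g"),
             mu_en_rho = interp_coeff(energy_keV, "mu_en_rho_cm2g"),
             buildup_a = stats::approx(water_coefficient_table()$energy_keV,
                                       water_coefficient_table()$buildup_a,
                                       xout = energy_keV, rule = 2)$y)
}

#' Linear attenuation coefficient of water at 140.5 keV (cm^-1)
#'
#' Convenience constant used for CT-derived attenuation maps of soft tissue
#' in Tc-99m imaging.
#' @export
mu_water_140kev <- function() {
  interp_coeff(140.511, "mu_rho_cm2g")  # rho = 1 g/mL
}
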