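#' Diffusion arithmetic for membrane-permeant dyes
#'
#' Back-of-the-envelope transport physics used when interpreting regional
#' uptake kinetics: mean-squared-displacement diffusion times, Stokes-Einstein
#' diffusion coefficients, and relative dye mobilities.
#'
#' @name physics
#' @keywords internal
NULL

#' Time to diffuse a given distance
#'
#' Inverts the Einstein-Smoluchowski mean-squared-displacement relation
#' \eqn{\langle x^2 \rangle = 2 n D t} to estimate how long a molecule with
#' diffusion coefficient `D` needs to spread over `distance`.
#'
#' The dimensionality factor `msd_factor` (2, 4 or 6 for 1-D, 2-D, 3-D) is a
#' required argument with no default: published estimates for intracellular
#' spreading are sometimes quoted with the 3-D form while the printed numbers
#' follow the factor-4 convention, so the caller must state which convention
#' is intended (see the methods vignette).
#'
#' @param distance distance in metres (> 0).
#' @param D diffusion coefficient in m^2 s^-1 (> 0).
#' @param msd_factor one of 2, 4, 6.
#' @return time in seconds.
#' @examples
#' # a 12 um cell, free cytosol (1e-10 m2/s), 2-D convention: ~0.36 s
#' diffusion_time(12e-6, 1e-10, msd_factor = 4)
#' @export
diffusion_time <- function(distance, D, msd_factor) {
  if (missing(msd_factor)) {
    stop("'msd_factor' must be given explicitly (2, 4 or 6); there is no default")
  }
  if (!msd_factor %in% c(2, 4, 6)) {
    stop("'msd_factor' must be 2 (1-D), 4 (2-D) or 6 (3-D)")
  }
  if (any(distance <= 0) || any(D <= 0)) {
    stop("'distance' and 'D' must be positive")
  }
  distance^2 / (msd_factor * D)
}

#' Stokes-Einstein diffusion coefficient
#'
#' \eqn{D = k_B T / (6 \pi \eta r)} for a sphere of hydrodynamic radius
#' `radius` in a fluid of viscosity `viscosity`.
#'
#' @param radius hydrodynamic radius in metres.
#' @param temperature absolute temperature in kelvin. Default 298 K.
#' @param viscosity dynamic viscosity in Pa s. Default 8.9e-4 (water, 25 C).
#' @return diffusion coefficient in m^2 s^-1.
#' @export
stokes_einstein_D <- function(radius, temperature = 298, viscosity = 8.9e-4) {
  if (any(radius <= 0) || any(temperature <= 0) || any(viscosity <= 0)) {
    stop("'radius', 'temperature' and 'viscosity' must be positive")
  }
  kB <- 1.380649e-23 # J/K, exact (SI 2019)
  kB * temperature / (6 * pi * viscosity * radius)
}

#' Bundled dye property table
#'
#' Molecular properties of the three uptake indicators handled by the
#' pipeline: YO-PRO-1 ("YP1", +2, 375 Da), propidium ("Pr", +2, 414 Da) and
#' calcein (-4, 622 Da), with approximate cylindrical cross-section diameters
#' (1.1, 1.4, 1.2 nm) and, for the intercalating dyes, geometry-based
#' intracellular diffusion coefficients (4.2e-10 and 3.2e-10 m^2 s^-1).
#'
#' @return data.frame with columns name, charge, mw_da, cross_section_nm,
#'   D_calc_m2s.
#' @export
dye_properties <- function() {
  path <- system.file("extdata", "dye_properties.csv", package = "poredirection")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Molecule geometry descriptor
#'
#' @param name dye name.
#' @param cross_section_diameter_nm cylindrical cross-section diameter, nm.
#' @param D_calc geometry-based diffusion coefficient, m^2 s^-1 (or NA).
#' @param mw molecular weight, Da (optional).
#' @return object of class `molecule_geometry`.
#' @export
molecule_geometry <- function(name, cross_section_diameter_nm = NA_real_,
                              D_calc = NA_real_, mw = NA_real_) {
  if (!is.na(cross_section_diameter_nm) && cross_section_diameter_nm <= 0) {
    stop("'cross_section_diameter_nm' must be positive")
  }
  structure(list(name = name,
                 cross_section_diameter_nm = cross_section_diameter_nm,
                 D_calc = D_calc, mw = mw),
            class = "molecule_geometry")
}

#' Look up a bundled dye as a molecule_geometry
#'
#' @param name one of "YP1", "Pr", "calcein" (case-insensitive; "YO-PRO-1"
#'   and "propidium" are accepted aliases).
#' @return a [molecule_geometry()].
#' @export
dye_geometry <- function(name) {
  tab <- dye_properties()
  key <- switch(tolower(name),
                "yp1" = , "yo-pro-1" = "YP1",
                "pr" = , "propidium" = "Pr",
                "calcein" = "calcein",
                stop("unknown dye: ", name))
  row <- tab[tab$name == key, ]
  molecule_geometry(row$name, row$cross_section_nm, row$D_calc_m2s, row$mw_da)
}

#' Relative mobility of two molecules
#'
#' Ratio of diffusion coefficients D_a / D_b, reported to 2 significant
#' figures. Uses geometry-based coefficients when both are present;
#' otherwise falls back to the Stokes-Einstein inverse-radius route from the
#' cross-section diameters (temperature and viscosity cancel).
#'
#' @param a,b [molecule_geometry()] objects.
#' @return dimensionless ratio, 2 significant figures.
#' @export
mobility_ratio <- function(a, b) {
  stopifnot(inherits(a, "molecule_geometry"), inherits(b, "molecule_geometry"))
  if (!is.na(a$D_calc) && !is.na(b$D_calc)) {
    r <- a$D_calc / b$D_calc
  } else if (!is.na(a$cross_section_diameter_nm) &&
             !is.na(b$cross_section_diameter_nm)) {
    # D ~ 1/r, so the ratio is the inverse radius (diameter) ratio
    r <- b$cross_section_diameter_nm / a$cross_section_diameter_nm
  } else {
    stop("need D_calc on both molecules, or cross-sections on both")
  }
  signif(r, 2)
}
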