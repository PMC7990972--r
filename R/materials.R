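# Material definitions: elemental compositions, densities and the quantities
# electron transport derives from them (effective Z/A, mean excitation energy,
# radiation length).

# Z/A per element (dimensionless)
.z_over_a <- c(H = 0.99212, C = 0.49954, N = 0.49976, O = 0.50002,
               S = 0.49897, P = 0.48428, Au = 0.40108)

# radiation lengths, g/cm^2
.x0_water_gcm2 <- 36.08
.x0_gold_gcm2 <- 6.46

#' Define a material for electron transport
#'
#' A material is described by its density, elemental mass fractions and mean
#' excitation energy I. Collision stopping powers and CSDA ranges are derived
#' from these with [stopping_power()] and [csda_range()].
#'
#' @param name Label.
#' @param density Mass density in g/cm^3.
#' @param mass_fractions Named numeric vector of elemental mass fractions
#'   (elements among H, C, N, O, S, P, Au); must sum to 1.
#' @param mean_excitation_energy Mean excitation energy I in eV.
#' @param x0_gcm2 Radiation length in g/cm^2 (used by the Highland multiple
#'   scattering width). Defaults to the water value for light media.
#' @return An object of class `material`.
#' @export
material <- function(name, density, mass_fractions, mean_excitation_energy,
                     x0_gcm2 = .x0_water_gcm2) {
  if (density <= 0) abort("density must be positive")
  if (mean_excitation_energy <= 0) {
    abort("mean_excitation_energy must be positive")
  }
  unknown <- setdiff(names(mass_fractions), names(.z_over_a))
  if (length(unknown) > 0) {
    abort(paste0("unknown elements: ", paste(unknown, collapse = ", ")))
  }
  if (abs(sum(mass_fractions) - 1) > 1e-9) {
    abort("mass fractions must sum to 1 (within 1e-9)")
  }
  structure(
    list(name = name, density = density,
         mass_fractions = mass_fractions,
         mean_excitation_energy = mean_excitation_energy,
         x0_gcm2 = x0_gcm2),
    class = "material"
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s: rho = %g g/cm^3, I = %g eV\n",
              x$name, x$density, x$mean_excitation_energy))
  invisible(x)
}

# effective Z/A = sum_i w_i (Z/A)_i
z_over_a_eff <- function(mat) {
  sum(mat$mass_fractions * .z_over_a[names(mat$mass_fractions)])
}

#' Water-equivalent transport medium
#'
#' All cell compartments are transported as unit-density water with a mean
#' excitation energy of 78 eV; the tabulated per-organelle compositions differ
#' from water by less than 2% in stopping power and are kept for bookkeeping
#' only.
#'
#' @return A `material`.
#' @export
water_material <- function() {
  material("water_equivalent", 1.0, c(H = 0.1119, O = 0.8881), 78,
           x0_gcm2 = .x0_water_gcm2)
}

#' Bulk gold (nanoparticle medium)
#' @return A `material`.
#' @export
gold_material <- function() {
  material("gold", 19.32, c(Au = 1), 790, x0_gcm2 = .x0_gold_gcm2)
}

#' CHO cell compartment compositions
#'
#' Elemental mass fractions (percent by mass, density 1.0 g/cm^3) of the
#' cytosol, nucleus, mitochondria and membrane of the model CHO cell, plus
#' bulk gold for the nanoparticles. These compositions are stored with the
#' geometry; electron transport itself uses the water-equivalent medium (see
#' [water_material()]).
#'
#' @return Named list of `material` objects keyed by region role.
#' @export
cho_materials <- function() {
  list(
    cytosol = material(
      "cytosol", 1.0,
      c(H = 0.1025, C = 0.1225, N = 0.0425, O = 0.7325), 78),
    nucleus = material(
      "nucleus", 1.0,
      c(H = 0.1060, C = 0.0900, N = 0.0320, O = 0.7420, S = 0.0040,
        P = 0.0260), 78),
    mitochondrion = material(
      "mitochondrion", 1.0,
      c(H = 0.1060, C = 0.0900, N = 0.0320, O = 0.7420, S = 0.0040,
        P = 0.0260), 78),
    membrane = material(
      "membrane", 1.0,
      c(H = 0.1025, C = 0.1225, N = 0.0425, O = 0.7325), 78),
    nanoparticle = gold_material()
  )
}

#' Cytosol medium with admixed gold (continuous model)
#'
#' In the continuous model the gold is not resolved as particles but mixed
#' homogeneously into the cytosol. The stopping power of the mixture follows
#' Bragg additivity of the water and gold mass stopping powers; the density is
#' the inverse-mixture of the component densities.
#'
#' @param gold_mass_fraction Gold mass fraction of the cytosol medium (0-1).
#' @return A `material` with a `components` attribute driving Bragg mixing.
#' @export
gold_loaded_cytosol <- function(gold_mass_fraction) {
  stopifnot(gold_mass_fraction >= 0, gold_mass_fraction < 1)
  w <- gold_mass_fraction
  water <- water_material()
  gold <- gold_material()
  density <- 1 / (w / gold$density + (1 - w) / water$density)
  x0 <- 1 / (w / gold$x0_gcm2 + (1 - w) / water$x0_gcm2)
  frac <- c(w * gold$mass_fractions["Au"], (1 - w) * water$mass_fractions)
  names(frac) <- c("Au", names(water$mass_fractions))
  m <- material("gold_loaded_cytosol", density, frac,
                water$mean_excitation_energy, x0_gcm2 = x0)
  attr(m, "components") <- list(
    list(material = water, weight = 1 - w),
    list(material = gold, weight = w)
  )
  m
}
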