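# Electron collision stopping power (Berger-Seltzer form of the Bethe
# formula), CSDA ranges, and the tabulated forms consumed by the compiled
# transport core. Energies in keV, stopping powers in eV/nm, ranges in mm.

.mc2_kev <- 511.0

# Berger-Seltzer collision stopping power for a single-I medium, MeV cm^2/g
bethe_mass_stopping <- function(energy_kev, i_ev, z_over_a) {
  tau <- energy_kev / .mc2_kev
  beta2 <- 1 - 1 / (1 + tau)^2
  i_mc2 <- (i_ev * 1e-3) / .mc2_kev
  f <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  0.153536 / beta2 * z_over_a * (log(tau^2 * (tau + 2) / (2 * i_mc2^2)) + f)
}

# mass stopping power (MeV cm^2/g) with the low-energy power-law extension:
# below 10 keV the Bethe expression is replaced by S(10 keV) * (E/10)^p with
# p matching the log-log slope at 10 keV, keeping S continuous and positive
mass_stopping_single <- function(energy_kev, i_ev, z_over_a) {
  e_match <- 10
  s <- ifelse(energy_kev >= e_match,
              bethe_mass_stopping(pmax(energy_kev, e_match), i_ev, z_over_a),
              NA_real_)
  low <- energy_kev < e_match
  if (any(low)) {
    h <- 1e-3
    s0 <- bethe_mass_stopping(e_match, i_ev, z_over_a)
    slope <- (log(bethe_mass_stopping(e_match * (1 + h), i_ev, z_over_a)) -
                log(bethe_mass_stopping(e_match * (1 - h), i_ev, z_over_a))) /
      (log(1 + h) - log(1 - h))
    s[low] <- s0 * (energy_kev[low] / e_match)^slope
  }
  s
}

# mass stopping power of a material, honouring Bragg-additive mixtures
mass_stopping <- function(energy_kev, mat) {
  comp <- attr(mat, "components")
  if (!is.null(comp)) {
    Reduce(`+`, lapply(comp, function(cc) {
      cc$weight * mass_stopping(energy_kev, cc$material)
    }))
  } else {
    mass_stopping_single(energy_kev, mat$mean_excitation_energy,
                         z_over_a_eff(mat))
  }
}

#' Electron collision stopping power
#'
#' Bethe collision stopping power (Berger-Seltzer form) for electrons of the
#' given kinetic energy in a material, evaluated with the material's mean
#' excitation energy and effective Z/A. Below 10 keV a power-law extension
#' matched in value and log-slope at 10 keV is used. For mixture materials
#' (see [gold_loaded_cytosol()]) the mass stopping powers of the components
#' are combined by Bragg additivity.
#'
#' @param energy_kev Electron kinetic energy in keV (vectorised, > 0).
#' @param material A [material()].
#' @return Linear stopping power in eV/nm.
#' @export
stopping_power <- function(energy_kev, material) {
  if (any(energy_kev <= 0)) abort("energy must be positive")
  # MeV cm^2/g * g/cm^3 = MeV/cm = 1e6 eV / 1e7 nm
  mass_stopping(energy_kev, material) * material$density * 0.1
}

#' CSDA range of an electron
#'
#' Continuous-slowing-down-approximation path length, the integral of
#' 1/S(E') from the tracking cutoff up to the starting energy.
#'
#' @param energy_kev Starting kinetic energy in keV (vectorised).
#' @param material A [material()].
#' @param cutoff_kev Lower integration limit in keV (default 1, the transport
#'   cutoff). Energies at or below the cutoff have zero range.
#' @return Range in mm.
#' @export
csda_range <- function(energy_kev, material, cutoff_kev = 1) {
  vapply(energy_kev, function(e) {
    if (e <= cutoff_kev) return(0)
    # integrate on a log grid; 1/S is smooth in log E
    val <- stats::integrate(
      function(u) exp(u) / stopping_power(exp(u), material),
      log(cutoff_kev), log(e), rel.tol = 1e-8
    )$value
    val * 1e3 / 1e6  # keV/(eV/nm) = 1e3 nm -> mm
  }, numeric(1))
}

# cumulative trapezoid
cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

# tabulated stopping/range representation used by the compiled core:
# log-spaced energy grid, log S, CSDA range (nm, measured from the table
# floor) and the radiation length in nm
material_table <- function(mat, e_min = 0.2, e_max = 2000, n = 6000) {
  e <- exp(seq(log(e_min), log(e_max), length.out = n))
  s <- stopping_power(e, mat)                 # eV/nm
  r <- cumtrapz(e, 1e3 / s)                   # nm
  list(logE = log(e), logS = log(s), range_nm = r,
       x0_nm = mat$x0_gcm2 / mat$density * 1e7)
}

# embedded water photon attenuation at the three gamma line energies;
# mu/rho and muen/rho in cm^2/g, log-log interpolated by the core
.photon_table <- list(
  energy_kev = c(412, 676, 1088),
  mu_over_rho = c(0.1048, 0.0848, 0.0678),
  muen_over_rho = c(0.0328, 0.0326, 0.0307)
)

#' Water photon attenuation coefficients
#'
#' Total attenuation and the energy-absorption fraction used by the
#' single-interaction photon model, log-log interpolated from an embedded
#' three-point table anchored at the 412, 676 and 1088 keV gamma lines.
#'
#' @param energy_kev Photon energy in keV, within \[100, 2000\].
#' @return Tibble with `mu_per_nm` (linear attenuation in water, 1/nm) and
#'   `muen_over_mu` (locally deposited fraction per interaction).
#' @export
photon_attenuation <- function(energy_kev) {
  if (any(energy_kev < 100 | energy_kev > 2000)) {
    abort("photon energy outside supported range [100, 2000] keV")
  }
  tab <- .photon_table
  logmu <- stats::approx(log(tab$energy_kev), log(tab$mu_over_rho),
                         log(energy_kev), rule = 2)$y
  frac <- stats::approx(log(tab$energy_kev),
                        tab$muen_over_rho / tab$mu_over_rho,
                        log(energy_kev), rule = 2)$y
  tibble::tibble(
    energy_kev = energy_kev,
    mu_per_nm = exp(logmu) * 1.0 / 1e7,  # rho = 1 g/cm^3, cm -> nm
    muen_over_mu = frac
  )
}
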