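# The 198Au decay source: nuclide constants, allowed-shape beta spectrum,
# per-decay emission sampling and decay-position sampling for the discrete
# (in-nanoparticle) and continuous (in-cytosol) source modes.

#' Define a radionuclide
#'
#' @param name Nuclide label.
#' @param isotope_mass Isotope mass in u (1 u = 1 g/mol for specific
#'   activity).
#' @param half_life_days Half-life in days (> 0); 1 day = 86400 s.
#' @param beta_lines Tibble with columns `energy_kev` (endpoint energies) and
#'   `intensity`; intensities must sum to 1 (exactly one beta per decay).
#' @param gamma_lines Tibble with columns `energy_kev` and `intensity`; each
#'   gamma line is emitted independently with its intensity.
#' @return A `nuclide_spec`.
#' @export
nuclide_spec <- function(name, isotope_mass, half_life_days, beta_lines,
                         gamma_lines) {
  stopifnot(half_life_days > 0, isotope_mass > 0)
  stopifnot(all(beta_lines$energy_kev > 0), all(beta_lines$intensity > 0),
            all(gamma_lines$energy_kev > 0), all(gamma_lines$intensity > 0),
            all(gamma_lines$intensity <= 1))
  if (abs(sum(beta_lines$intensity) - 1) > 1e-9) {
    abort("beta intensities must sum to 1")
  }
  structure(
    list(name = name, isotope_mass = isotope_mass,
         half_life_days = half_life_days,
         beta_lines = beta_lines, gamma_lines = gamma_lines),
    class = "nuclide_spec"
  )
}

#' The 198Au nuclide
#'
#' Radioactive gold: half-life 2.7 days, isotope mass 198 u, beta-minus
#' decay to stable 198Hg with endpoint energies 961 keV (99%) and 285 keV
#' (1%), and gamma lines at 412 keV (96%), 676 keV and 1088 keV. The two
#' minor gamma lines are only bounded ("<1%") in the nuclide records used
#' here; their default intensity is the upper bound 0.01 and can be
#' overridden.
#'
#' @param minor_gamma_intensity Intensity assigned to the 676 and 1088 keV
#'   lines.
#' @return A [nuclide_spec()].
#' @export
au198_spec <- function(minor_gamma_intensity = 0.01) {
  nuclide_spec(
    name = "Au-198", isotope_mass = 198, half_life_days = 2.7,
    beta_lines = tibble::tibble(energy_kev = c(961, 285),
                                intensity = c(0.99, 0.01)),
    gamma_lines = tibble::tibble(
      energy_kev = c(412, 676, 1088),
      intensity = c(0.96, minor_gamma_intensity, minor_gamma_intensity))
  )
}

#' Specific activity of a radionuclide
#'
#' `ln(2) / T_half[s] * N_A / M[g/mol]`, the decay rate per gram of the pure
#' nuclide.
#'
#' @param spec A [nuclide_spec()].
#' @return Specific activity in Bq/g.
#' @export
specific_activity <- function(spec) {
  lambda <- log(2) / (spec$half_life_days * 86400)
  lambda * 6.02214076e23 / spec$isotope_mass
}

#' Sample beta energies from the allowed spectrum shape
#'
#' Rejection sampling from `N(E) ~ p * W * (Q - E)^2` with W the total
#' energy, p the momentum and Q the endpoint (no Fermi-Coulomb correction).
#' Support is (0, Q].
#'
#' @param endpoint_kev Endpoint (maximum) energy Q in keV.
#' @param n Number of samples.
#' @param monoenergetic If `TRUE`, return the endpoint energy exactly
#'   (debugging mode).
#' @return Numeric vector of energies in keV.
#' @export
sample_beta_energy <- function(endpoint_kev, n = 1, monoenergetic = FALSE) {
  stopifnot(endpoint_kev > 0)
  if (monoenergetic) return(rep(endpoint_kev, n))
  cpp_sample_beta(as.integer(n), endpoint_kev)
}

iso_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(dx = s * cos(phi), dy = s * sin(phi), dz = z)
}

#' Sample the emissions of radioactive decays
#'
#' Each decay emits exactly one beta particle (branch chosen by intensity,
#' energy from [sample_beta_energy()]) and each gamma line independently with
#' its intensity. All emission directions are isotropic.
#'
#' @param spec A [nuclide_spec()].
#' @param n Number of decays.
#' @param monoenergetic_beta Emit betas at their endpoint energy.
#' @return Tibble with columns `decay`, `kind` (`"beta"`/`"gamma"`),
#'   `energy_kev`, `dx`, `dy`, `dz`.
#' @export
sample_emissions <- function(spec, n = 1, monoenergetic_beta = FALSE) {
  bl <- spec$beta_lines
  branch <- sample.int(nrow(bl), n, replace = TRUE, prob = bl$intensity)
  be <- numeric(n)
  for (b in unique(branch)) {
    idx <- branch == b
    be[idx] <- sample_beta_energy(bl$energy_kev[b], sum(idx),
                                  monoenergetic_beta)
  }
  betas <- tibble::tibble(decay = seq_len(n), kind = "beta",
                          energy_kev = be)
  gl <- spec$gamma_lines
  gammas <- purrr::map_dfr(seq_len(nrow(gl)), function(i) {
    hit <- which(runif(n) < gl$intensity[i])
    tibble::tibble(decay = hit, kind = "gamma",
                   energy_kev = rep(gl$energy_kev[i], length(hit)))
  })
  out <- dplyr::arrange(dplyr::bind_rows(betas, gammas), .data$decay)
  dirs <- iso_directions(nrow(out))
  dplyr::bind_cols(out, tibble::as_tibble(dirs))
}

#' Sample radioactive decay positions
#'
#' Discrete mode: a nanoparticle is chosen volume-weighted (uniformly when
#' all share one radius) and the decay position is uniform within it.
#' Continuous mode: the position is uniform over the cytosol.
#'
#' @param geom A `cell_geometry`.
#' @param mode `"discrete"` or `"continuous"`.
#' @param n Number of positions.
#' @return An `n` x 3 matrix of coordinates (nm).
#' @export
sample_decay_position <- function(geom, mode = c("discrete", "continuous"),
                                  n = 1) {
  mode <- match.arg(mode)
  if (mode == "continuous") {
    return(sample_point_in_cytosol(geom, n))
  }
  np <- geom$spheres[geom$spheres$role == "nanoparticle", ]
  if (nrow(np) == 0) {
    abort("discrete source mode requires at least one nanoparticle")
  }
  w <- np$radius^3
  idx <- sample.int(nrow(np), n, replace = TRUE, prob = w)
  offs <- sample_point_in_sphere(c(0, 0, 0), 1, n) * np$radius[idx]
  cbind(np$x[idx], np$y[idx], np$z[idx]) + offs
}
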