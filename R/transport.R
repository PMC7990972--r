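# R-facing surface of the condensed-step transport surrogate. Electrons lose
# energy continuously along condensed steps (CSDA on tabulated ranges),
# limited to 5% of the remaining range, the distance to the next region
# boundary and a maximum step; after each step the direction is deflected by
# a Gaussian polar angle of Highland width. Photons either escape or undergo
# at most one interaction sampled from the water attenuation coefficient.

#' Transport configuration
#'
#' @param step_fraction Fraction of the remaining CSDA range per condensed
#'   step (0 < f <= 1, default 0.05).
#' @param energy_cutoff Tracking cutoff in keV (default 1); the residual
#'   energy is deposited in the region of the current position.
#' @param multiple_scattering Apply Highland multiple scattering after each
#'   step (default `TRUE`).
#' @param photon_mode `"single_interaction"` (default) or `"escape"`.
#' @param max_step Maximum condensed step length in nm.
#' @param monoenergetic_beta Emit betas at their endpoint energy (debugging).
#' @return A `transport_config`.
#' @export
transport_config <- function(step_fraction = 0.05, energy_cutoff = 1,
                             multiple_scattering = TRUE,
                             photon_mode = c("single_interaction", "escape"),
                             max_step = 1e4, monoenergetic_beta = FALSE) {
  photon_mode <- match.arg(photon_mode)
  stopifnot(step_fraction > 0, step_fraction <= 1, energy_cutoff > 0,
            max_step > 0)
  structure(
    list(step_fraction = step_fraction, energy_cutoff = energy_cutoff,
         multiple_scattering = multiple_scattering,
         photon_mode = photon_mode, max_step = max_step,
         monoenergetic_beta = monoenergetic_beta),
    class = "transport_config"
  )
}

cfg_to_cpp <- function(cfg) {
  tab <- .photon_table
  list(
    step_fraction = cfg$step_fraction,
    energy_cutoff = cfg$energy_cutoff,
    max_step = cfg$max_step,
    multiple_scattering = cfg$multiple_scattering,
    photon_mode_int = if (cfg$photon_mode == "escape") 0L else 1L,
    photon_log_e = log(tab$energy_kev),
    photon_log_mu = log(tab$mu_over_rho * 1.0 / 1e7),  # 1/nm at 1 g/cm^3
    photon_muen_frac = tab$muen_over_rho / tab$mu_over_rho,
    monoenergetic_beta = cfg$monoenergetic_beta
  )
}

# material tables + role mapping for the compiled core.
# All cell compartments are transported as water; nanoparticles as gold; in
# the continuous model the cytosol medium carries the admixed gold.
.table_cache <- new.env(parent = emptyenv())

cached_table <- function(key, mat) {
  tab <- .table_cache[[key]]
  if (is.null(tab)) {
    tab <- material_table(mat)
    assign(key, tab, envir = .table_cache)
  }
  tab
}

transport_state <- function(geom, gold_mass_percent = 0) {
  mats <- list(cached_table("water", water_material()),
               cached_table("gold", gold_material()))
  # roles: outside, membrane, cytosol, nucleus, mitochondrion, nanoparticle
  mat_role <- c(0L, 0L, 0L, 0L, 0L, 1L)
  if (gold_mass_percent > 0) {
    w <- gold_fraction_of_cytosol(geom, gold_mass_percent)
    mats[[3]] <- cached_table(sprintf("mix_%.15g", w),
                              gold_loaded_cytosol(w))
    mat_role[3] <- 2L
  }
  g <- geom_to_cpp(geom)
  g$materials <- mats
  g$mat_role <- mat_role
  g
}

# convert a whole-cell gold mass percentage into the gold mass fraction of
# the cytosol medium (cytosol volume = inner ball minus organelles)
gold_fraction_of_cytosol <- function(geom, gold_mass_percent) {
  sp <- geom$spheres
  v_cell <- (4 / 3) * pi * geom$cell_radius^3
  v_in <- (4 / 3) * pi * inner_radius(geom)^3
  v_org <- sum((4 / 3) * pi * sp$radius^3)
  m_gold <- gold_mass_percent / 100 * v_cell * 1.0   # rho_cell = 1 g/cm^3
  m_cyt <- (v_in - v_org) * 1.0
  m_gold / (m_gold + m_cyt)
}

deposit_tibble <- function(dep, escaped) {
  tibble::tibble(
    region = c(.region_roles[-1], "escaped"),
    energy_ev = c(dep[-1], escaped)
  )
}

#' Transport a single electron
#'
#' @param geom A `cell_geometry`.
#' @param position Numeric length-3 start point (nm).
#' @param direction Unit direction vector.
#' @param energy_kev Kinetic energy in keV (> 0).
#' @param cfg A [transport_config()].
#' @param gold_mass_percent Whole-cell gold mass percentage mixed into the
#'   cytosol medium (continuous model; default 0).
#' @return Tibble of energy deposits with columns `region` and `energy_ev`;
#'   the `escaped` row holds the energy leaving the cell.
#' @export
transport_electron <- function(geom, position, direction, energy_kev,
                               cfg = transport_config(),
                               gold_mass_percent = 0) {
  res <- cpp_transport_electron(
    transport_state(geom, gold_mass_percent),
    as.numeric(position), as.numeric(direction), energy_kev,
    cfg_to_cpp(cfg))
  deposit_tibble(res$deposit_ev, res$escaped_ev)
}

#' Transport a single photon
#'
#' @inheritParams transport_electron
#' @param energy_kev Photon energy in keV, within \[100, 2000\].
#' @return Tibble of energy deposits (see [transport_electron()]).
#' @export
transport_photon <- function(geom, position, direction, energy_kev,
                             cfg = transport_config()) {
  res <- cpp_transport_photon(
    transport_state(geom), as.numeric(position), as.numeric(direction),
    energy_kev, cfg_to_cpp(cfg))
  deposit_tibble(res$deposit_ev, res$escaped_ev)
}

#' Simulate radioactive decays and tally energy deposits
#'
#' For each decay: the position is sampled (inside a nanoparticle in the
#' discrete mode, uniformly in the cytosol in the continuous mode), the
#' emissions are sampled (one beta plus independent gamma lines), and every
#' emission is transported through the geometry. Deposits are accumulated
#' per region role.
#'
#' @param geom A `cell_geometry`.
#' @param n_decays Number of decays (>= 1).
#' @param mode `"discrete"` or `"continuous"`.
#' @param nuclide A [nuclide_spec()] (default [au198_spec()]).
#' @param cfg A [transport_config()].
#' @param gold_mass_percent Whole-cell gold mass percentage admixed to the
#'   cytosol (continuous model).
#' @return An `energy_tally`.
#' @export
simulate_decays <- function(geom, n_decays,
                            mode = c("discrete", "continuous"),
                            nuclide = au198_spec(),
                            cfg = transport_config(),
                            gold_mass_percent = 0) {
  mode <- match.arg(mode)
  stopifnot(n_decays >= 1)
  nuc <- list(
    beta_energies = nuclide$beta_lines$energy_kev,
    beta_intensities = nuclide$beta_lines$intensity,
    gamma_energies = nuclide$gamma_lines$energy_kev,
    gamma_intensities = nuclide$gamma_lines$intensity
  )
  res <- cpp_simulate_decays(
    transport_state(geom, gold_mass_percent), nuc, cfg_to_cpp(cfg),
    as.integer(n_decays), if (mode == "discrete") 0L else 1L)
  dep <- res$deposit_ev
  energy <- setNames(dep[-1], .region_roles[-1])
  structure(
    list(n_decays = n_decays,
         energy_ev = energy,
         escaped_ev = res$escaped_ev,
         emitted_ev = res$emitted_ev,
         mode = mode,
         gold_mass_percent = gold_mass_percent),
    class = "energy_tally"
  )
}

#' @export
print.energy_tally <- function(x, ...) {
  cat(sprintf("<energy_tally> %d decays (%s mode), cell %0.4g eV/decay\n",
              x$n_decays, x$mode, sum(x$energy_ev) / x$n_decays))
  invisible(x)
}

# scoring regions derived from a tally. Following the reference convention,
# "cytosol" includes the nanoparticle deposit (the nanoparticles sit in the
# cytosol); "cytosol_no_np" excludes it; "cell" is the sum of everything
# inside the outer membrane surface.
tally_regions <- function(tally) {
  e <- tally$energy_ev
  c(cell = sum(e),
    cytosol = e[["cytosol"]] + e[["nanoparticle"]],
    cytosol_no_np = e[["cytosol"]],
    nucleus = e[["nucleus"]],
    mitochondria = e[["mitochondrion"]],
    membrane = e[["membrane"]],
    nanoparticles = e[["nanoparticle"]])
}

#' @export
tidy.energy_tally <- function(x, ...) {
  v <- tally_regions(x)
  tibble::tibble(region = names(v), energy_ev = unname(v),
                 ev_per_decay = unname(v) / x$n_decays)
}

#' Run repeated simulation batches with derived seeds
#'
#' Runs `n_batches` independent simulations of `n_decays` decays each; batch
#' `i` uses RNG seed `base_seed + i`, so batches are reproducible and
#' statistically independent.
#'
#' @inheritParams simulate_decays
#' @param n_batches Number of batches.
#' @param base_seed Integer seed root.
#' @return List of `energy_tally` objects (class `tally_batches`).
#' @export
run_batches <- function(geom, n_decays, n_batches, base_seed,
                        mode = c("discrete", "continuous"),
                        nuclide = au198_spec(), cfg = transport_config(),
                        gold_mass_percent = 0) {
  mode <- match.arg(mode)
  out <- lapply(seq_len(n_batches), function(i) {
    set.seed(base_seed + i)
    simulate_decays(geom, n_decays, mode, nuclide, cfg, gold_mass_percent)
  })
  class(out) <- "tally_batches"
  out
}
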