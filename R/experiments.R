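# The canned experiments: continuous-gold mass sweep, discrete nanoparticle
# radii, the nucleus-targeting sweep, and the mass-independence check of the
# targeting enhancement. Each experiment writes summary/enhancement CSVs, a
# machine-readable manifest (a re-runnable config) and a log into the output
# directory.

condition_seed <- function(base_seed, j) base_seed + 100000 * j

#' Run a configured experiment
#'
#' Dispatches on `config$experiment`:
#' \describe{
#'   \item{continuous_sweep}{Continuous gold model at whole-cell gold mass
#'     percentages 0.001, 0.01, 0.1 and 1.}
#'   \item{discrete_radii}{`n_np` cytosol-random nanoparticles with radii 3,
#'     4 and 5 nm.}
#'   \item{targeting_sweep}{Nucleus-targeting sweep over `x_values` at fixed
#'     `n_np` x `r_np`.}
#'   \item{mass_independence}{E_rel(100%) vs E(0%) for nanoparticle loads
#'     from 10^4 x 3 nm up to 4x10^4 x 5 nm (gold mass percentages 0.0024%
#'     to 0.044%).}
#' }
#' Every condition runs `n_batches` batches with seeds derived from
#' `base_seed` (see [run_targeting_sweep()] for the scheme). Outputs:
#' `summary.csv` (one row per region per condition), `enhancement.csv`
#' (where applicable), `fits.csv` (targeting sweep), `manifest.txt` and
#' `run.log`.
#'
#' @param config A `run_config` from [read_run_config()].
#' @param out_dir Output directory (default `config$output_dir`); created if
#'   missing.
#' @return Invisibly, a list with the result objects and output paths.
#' @export
run_experiment <- function(config, out_dir = config$output_dir) {
  validate_run_config(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      abort(sprintf("cannot create output directory '%s'", out_dir))
    }
  }
  nuclide <- config_nuclide(config)
  tcfg <- config_transport(config)
  set.seed(config$base_seed)
  geom <- config_geometry(config)
  log_lines <- c(sprintf("experiment: %s", config$experiment),
                 sprintf("base_seed: %g", config$base_seed),
                 sprintf("n_decays: %g, n_batches: %g",
                         config$n_decays, config$n_batches))
  result <- switch(
    config$experiment,
    continuous_sweep = {
      m_values <- c(0.001, 0.01, 0.1, 1)
      rows <- purrr::imap_dfr(m_values, function(m, j) {
        s <- summarize_batches(run_batches(
          geom, config$n_decays, config$n_batches,
          base_seed = condition_seed(config$base_seed, j),
          mode = "continuous", nuclide = nuclide, cfg = tcfg,
          gold_mass_percent = m))
        dplyr::mutate(tibble::as_tibble(s), gold_mass_percent = m,
                      .before = 1)
      })
      list(summary = rows)
    },
    discrete_radii = {
      radii <- c(3, 4, 5)
      rows <- purrr::imap_dfr(radii, function(r, j) {
        cond <- condition_seed(config$base_seed, j)
        set.seed(cond)
        spec <- placement_spec(config$n_np, r)
        g <- place_nanoparticles(geom, spec)
        s <- summarize_batches(run_batches(
          g, config$n_decays, config$n_batches, base_seed = cond,
          mode = "discrete", nuclide = nuclide, cfg = tcfg))
        dplyr::mutate(tibble::as_tibble(s), r_np = r, n_np = config$n_np,
                      gold_mass_percent = gold_mass_percent(spec, geom),
                      .before = 1)
      })
      list(summary = rows)
    },
    targeting_sweep = {
      sweep <- run_targeting_sweep(
        geom = geom, x_values = config$x_values, n_np = config$n_np,
        r_np = config$r_np, n_decays = config$n_decays,
        n_batches = config$n_batches, base_seed = config$base_seed,
        target = config$target, nuclide = nuclide, cfg = tcfg)
      list(summary = sweep$energies, enhancement = tidy(sweep),
           fits = glance(sweep), sweep = sweep)
    },
    mass_independence = {
      conds <- tibble::tibble(n_np = c(1e4, 1e4, 1e4, 2e4, 4e4),
                              r_np = c(3, 4, 5, 5, 5))
      rows <- purrr::map_dfr(seq_len(nrow(conds)), function(j) {
        cond <- condition_seed(config$base_seed, j)
        spec1 <- placement_spec(conds$n_np[j], conds$r_np[j],
                                fraction_targeted = 1)
        spec0 <- placement_spec(conds$n_np[j], conds$r_np[j],
                                fraction_targeted = 0)
        set.seed(cond)
        g1 <- place_nanoparticles(geom, spec1)
        set.seed(cond + 50000)
        g0 <- place_nanoparticles(geom, spec0)
        s1 <- summarize_batches(run_batches(
          g1, config$n_decays, config$n_batches, base_seed = cond,
          mode = "discrete", nuclide = nuclide, cfg = tcfg))
        s0 <- summarize_batches(run_batches(
          g0, config$n_decays, config$n_batches, base_seed = cond + 50000,
          mode = "discrete", nuclide = nuclide, cfg = tcfg))
        dplyr::mutate(relative_enhancement(s1, s0),
                      m_aunp_percent = gold_mass_percent(spec1, geom),
                      n_np = conds$n_np[j], r_np = conds$r_np[j],
                      .before = 1)
      })
      list(enhancement = rows)
    }
  )
  paths <- list()
  if (!is.null(result$summary)) {
    paths$summary <- file.path(out_dir, "summary.csv")
    write.csv(result$summary, paths$summary, row.names = FALSE)
  }
  if (!is.null(result$enhancement)) {
    paths$enhancement <- file.path(out_dir, "enhancement.csv")
    write.csv(result$enhancement, paths$enhancement, row.names = FALSE)
  }
  if (!is.null(result$fits)) {
    paths$fits <- file.path(out_dir, "fits.csv")
    write.csv(result$fits, paths$fits, row.names = FALSE)
  }
  paths$manifest <- file.path(out_dir, "manifest.txt")
  write_run_config(config, paths$manifest)
  paths$log <- file.path(out_dir, "run.log")
  writeLines(c(log_lines, "status: complete"), paths$log)
  invisible(c(result, list(paths = paths)))
}
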