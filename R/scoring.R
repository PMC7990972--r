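# Aggregation of tallies into per-region eV/decay summaries with batch
# standard deviations, absorbed dose, relative enhancement E_rel and
# ordinary-least-squares linearity fits.

#' Summarise simulation batches
#'
#' Mean and sample standard deviation (n - 1 denominator) of the per-decay
#' energy deposit in each scoring region across batches. With a single batch
#' the standard deviation is reported as `NA`.
#'
#' @param batches List of `energy_tally` objects (e.g. from
#'   [run_batches()]) with equal `n_decays`.
#' @return A `run_summary` tibble with columns `region`,
#'   `mean_ev_per_decay`, `sd_ev_per_decay`, `n_batches`, `n_decays`.
#' @export
summarize_batches <- function(batches) {
  stopifnot(length(batches) >= 1)
  nd <- vapply(batches, function(b) b$n_decays, numeric(1))
  if (length(unique(nd)) != 1) {
    abort("all batches must have the same number of decays")
  }
  per <- vapply(batches, function(b) tally_regions(b) / b$n_decays,
                tally_regions(batches[[1]]))
  per <- matrix(per, nrow = 7,
                dimnames = list(names(tally_regions(batches[[1]]))))
  out <- tibble::tibble(
    region = rownames(per),
    mean_ev_per_decay = rowMeans(per),
    sd_ev_per_decay = if (length(batches) >= 2) {
      apply(per, 1, stats::sd)
    } else {
      NA_real_
    },
    n_batches = length(batches),
    n_decays = nd[1]
  )
  class(out) <- c("run_summary", class(out))
  out
}

#' Absorbed dose from a deposited energy
#'
#' @param energy_ev Total deposited energy in eV.
#' @param mass_kg Mass of the scoring region in kg (> 0).
#' @return Absorbed dose in Gy.
#' @export
dose_gy <- function(energy_ev, mass_kg) {
  if (any(mass_kg <= 0)) abort("mass must be positive")
  energy_ev * 1.602176634e-19 / mass_kg
}

#' Mass of a sphere
#'
#' @param radius_nm Radius in nm.
#' @param density_g_cm3 Density in g/cm^3 (default 1).
#' @return Mass in kg.
#' @export
sphere_mass_kg <- function(radius_nm, density_g_cm3 = 1) {
  (4 / 3) * pi * (radius_nm * 1e-7)^3 * density_g_cm3 * 1e-3
}

#' Mass of the whole cell sphere
#'
#' Whole-cell sphere at 1.0 g/cm^3; the gold mass (at most 0.04% of the
#' cell) is ignored.
#'
#' @param geom A `cell_geometry`.
#' @return Mass in kg.
#' @export
cell_mass_kg <- function(geom) sphere_mass_kg(geom$cell_radius, 1.0)

#' Relative energy deposit between two conditions
#'
#' `E_rel = 100% * E(x) / E(0%)` per region, where the baseline `E(0%)` is
#' the condition with all nanoparticles distributed randomly in the cytosol.
#'
#' @param summary_x,summary_0 `run_summary` tibbles covering the same
#'   regions.
#' @return Tibble with columns `region` and `e_rel_percent`.
#' @export
relative_enhancement <- function(summary_x, summary_0) {
  if (!setequal(summary_x$region, summary_0$region)) {
    abort("summaries must cover the same regions")
  }
  j <- dplyr::inner_join(summary_x, summary_0, by = "region",
                         suffix = c("_x", "_0"))
  if (any(j$mean_ev_per_decay_0 <= 0)) {
    abort("baseline energy deposit must be positive in every region")
  }
  tibble::tibble(
    region = j$region,
    e_rel_percent = 100 * j$mean_ev_per_decay_x / j$mean_ev_per_decay_0
  )
}

#' Ordinary least-squares linearity fit
#'
#' Fits `y = intercept + slope * x` and reports the coefficient of
#' determination `R^2 = 1 - SS_res / SS_tot`. When `SS_tot = 0` (constant
#' response, e.g. a perfectly flat sweep) `R^2` is defined as 1.
#'
#' @param x Predictor values (at least 3 distinct values).
#' @param y Response values.
#' @return Tibble with columns `slope`, `intercept`, `r_squared`.
#' @export
linearity_fit <- function(x, y) {
  if (length(unique(x)) < 3) {
    abort("linearity fit needs at least 3 distinct x values")
  }
  fit <- lm(y ~ x)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2)
}

#' @export
autoplot.run_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$region,
                                                  -.data$mean_ev_per_decay),
                               y = .data$mean_ev_per_decay)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_ev_per_decay - .data$sd_ev_per_decay,
                   ymax = .data$mean_ev_per_decay + .data$sd_ev_per_decay),
      width = 0.25) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "energy deposit (eV/decay)") +
    ggplot2::theme_minimal()
}
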