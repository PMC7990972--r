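# Nucleus-targeting sweep: vary the fraction x of nanoparticles attached to
# the nucleus surface at a constant total nanoparticle load, and score the
# relative energy deposit E_rel(x) = 100% * E(x) / E(0%) per region together
# with ordinary-least-squares linearity fits.

#' Run a nucleus-targeting sweep
#'
#' For each fraction `x` in `x_values`, `round(n_np * x)` nanoparticles are
#' attached to the target organelle surface and the rest are distributed
#' randomly in the cytosol; `n_batches` batches of `n_decays` 198Au decays
#' are then simulated in the discrete source mode. The baseline `E(0%)` is
#' the all-random condition, so `x_values` must contain 0.
#'
#' Seeds are derived deterministically from `base_seed`: condition `j` uses
#' `base_seed + 100000 * j` for nanoparticle placement and
#' `base_seed + 100000 * j + i` for batch `i`.
#'
#' @param geom A `cell_geometry` without nanoparticles (e.g. from
#'   [build_cho_cell()]). If `NULL`, the default CHO cell is built with seed
#'   `base_seed`.
#' @param x_values Targeted fractions; must include 0.
#' @param n_np Total number of nanoparticles.
#' @param r_np Nanoparticle radius in nm.
#' @param n_decays Decays per batch.
#' @param n_batches Batches per condition.
#' @param base_seed Integer seed root.
#' @param target Target organelle (`"nucleus"` or `"mitochondria"`).
#' @param nuclide A [nuclide_spec()].
#' @param cfg A [transport_config()].
#' @return An `enhancement_result` with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
run_targeting_sweep <- function(geom = NULL, x_values = seq(0, 1, by = 0.2),
                                n_np = 10000, r_np = 5, n_decays = 1e5,
                                n_batches = 10, base_seed = 1,
                                target = "nucleus",
                                nuclide = au198_spec(),
                                cfg = transport_config()) {
  if (!any(x_values == 0)) {
    abort("x_values must contain the x = 0 baseline")
  }
  if (is.null(geom)) {
    set.seed(base_seed)
    geom <- build_cho_cell()
  }
  summaries <- purrr::imap(x_values, function(x, j) {
    cond_seed <- base_seed + 100000 * j
    set.seed(cond_seed)
    g <- place_nanoparticles(
      geom, placement_spec(n_np, r_np, fraction_targeted = x,
                           target = target))
    summarize_batches(run_batches(
      g, n_decays, n_batches, base_seed = cond_seed,
      mode = "discrete", nuclide = nuclide, cfg = cfg))
  })
  energies <- purrr::map2_dfr(x_values, summaries, function(x, s) {
    dplyr::mutate(tibble::as_tibble(s), x = x, .before = 1)
  })
  s0 <- summaries[[which(x_values == 0)[1]]]
  e_rel <- purrr::map2_dfr(x_values, summaries, function(x, s) {
    dplyr::mutate(relative_enhancement(s, s0), x = x, .before = 1)
  })
  fits <- if (length(unique(x_values)) >= 3) {
    energies |>
      dplyr::group_by(.data$region) |>
      dplyr::group_modify(~ linearity_fit(.x$x, .x$mean_ev_per_decay)) |>
      dplyr::ungroup()
  }
  structure(
    list(x_values = x_values, n_np = n_np, r_np = r_np,
         n_decays = n_decays, n_batches = n_batches, target = target,
         energies = energies, e_rel = e_rel, fits = fits),
    class = "enhancement_result"
  )
}

#' @export
print.enhancement_result <- function(x, ...) {
  top <- x$e_rel[x$e_rel$x == max(x$x_values) &
                   x$e_rel$region %in% c("cell", "nucleus"), ]
  cat(sprintf(
    "<enhancement_result> %d x-points, %d x %g nm nanoparticles -> E_rel(%g): nucleus %.0f%%, cell %.0f%%\n",
    length(x$x_values), x$n_np, x$r_np, max(x$x_values),
    top$e_rel_percent[top$region == "nucleus"],
    top$e_rel_percent[top$region == "cell"]))
  invisible(x)
}

#' @export
tidy.enhancement_result <- function(x, ...) {
  dplyr::inner_join(x$energies, x$e_rel, by = c("x", "region"))
}

#' @export
glance.enhancement_result <- function(x, ...) {
  x$fits %||% tibble::tibble(region = character(), slope = numeric(),
                             intercept = numeric(), r_squared = numeric())
}

#' @export
autoplot.enhancement_result <- function(object, regions = c("cell",
                                                            "cytosol",
                                                            "nucleus",
                                                            "mitochondria",
                                                            "membrane"),
                                        ...) {
  d <- dplyr::filter(object$e_rel, .data$region %in% regions)
  ggplot2::ggplot(d, ggplot2::aes(x = 100 * .data$x,
                                  y = .data$e_rel_percent,
                                  colour = .data$region)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "nanoparticles attached to the nucleus (%)",
                  y = expression(E[rel] ~ "(%)")) +
    ggplot2::theme_minimal()
}
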