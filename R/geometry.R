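# The nested-sphere cell world: cell ball with an outer membrane shell,
# nucleus, mitochondria and gold nanoparticles, all spheres. Coordinates are
# in nm with the cell centre at the origin. The membrane occupies the
# outermost shell [cell_radius - membrane_thickness, cell_radius]; every
# organelle and nanoparticle must lie fully inside the inner membrane
# surface. Tangency (exact touching) does not count as overlap, which is what
# permits surface-attached nanoparticles.

new_cell_geometry <- function(cell_radius, membrane_thickness, spheres,
                              materials) {
  structure(
    list(cell_radius = cell_radius,
         membrane_thickness = membrane_thickness,
         spheres = spheres,
         materials = materials),
    class = "cell_geometry"
  )
}

empty_spheres <- function() {
  tibble::tibble(role = character(), id = integer(),
                 x = numeric(), y = numeric(), z = numeric(),
                 radius = numeric())
}

#' Inner membrane radius of a cell geometry
#' @param geom A `cell_geometry`.
#' @return Radius of the inner membrane surface in nm.
#' @export
inner_radius <- function(geom) geom$cell_radius - geom$membrane_thickness

#' @export
print.cell_geometry <- function(x, ...) {
  counts <- table(factor(x$spheres$role,
                         levels = c("nucleus", "mitochondrion",
                                    "nanoparticle")))
  cat(sprintf(
    "<cell_geometry> R = %g nm, membrane %g nm; %d nucleus, %d mitochondria, %d nanoparticles\n",
    x$cell_radius, x$membrane_thickness,
    counts[["nucleus"]], counts[["mitochondrion"]], counts[["nanoparticle"]]))
  invisible(x)
}

#' @export
as_tibble.cell_geometry <- function(x, ...) x$spheres

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

# list representation consumed by the compiled core
geom_to_cpp <- function(geom, materials_tables = NULL, mat_role = NULL) {
  sp <- geom$spheres
  nuc <- sp[sp$role == "nucleus", ]
  mito <- sp[sp$role == "mitochondrion", ]
  np <- sp[sp$role == "nanoparticle", ]
  out <- list(
    cell_radius = geom$cell_radius,
    inner_radius = inner_radius(geom),
    nucleus = if (nrow(nuc) > 0) {
      c(nuc$x[1], nuc$y[1], nuc$z[1], nuc$radius[1])
    },
    mito = if (nrow(mito) > 0) {
      cbind(mito$x, mito$y, mito$z, mito$radius)
    },
    np = if (nrow(np) > 0) cbind(np$x, np$y, np$z, np$radius)
  )
  if (!is.null(materials_tables)) {
    out$materials <- materials_tables
    out$mat_role <- mat_role
  } else {
    # geometry-only queries never touch the material tables
    out$materials <- list()
    out$mat_role <- integer(6)
  }
  out
}

#' Create a bare cell geometry
#'
#' A cell with a membrane shell and optionally a central nucleus, but no
#' mitochondria or nanoparticles; useful as a starting point for custom
#' worlds.
#'
#' @param cell_radius Outer cell radius in nm.
#' @param membrane_thickness Membrane shell thickness in nm.
#' @param nucleus_radius Nucleus radius in nm, or `NULL` for no nucleus.
#' @return A `cell_geometry`.
#' @export
cell_geometry <- function(cell_radius = 6000, membrane_thickness = 10,
                          nucleus_radius = NULL) {
  stopifnot(cell_radius > 0, membrane_thickness > 0,
            membrane_thickness < cell_radius)
  spheres <- empty_spheres()
  if (!is.null(nucleus_radius)) {
    stopifnot(nucleus_radius > 0,
              nucleus_radius <= cell_radius - membrane_thickness)
    spheres <- tibble::tibble(role = "nucleus", id = 1L, x = 0, y = 0,
                              z = 0, radius = nucleus_radius)
  }
  new_cell_geometry(cell_radius, membrane_thickness, spheres,
                    cho_materials())
}

#' Do two spheres overlap?
#'
#' Strict overlap test: spheres overlap iff the distance between centres is
#' smaller than the sum of radii. Tangent spheres (distance exactly equal) do
#' not overlap, so nanoparticles attached to an organelle surface are legal.
#'
#' @param c1,c2 Sphere centres, numeric length-3 vectors (nm).
#' @param r1,r2 Sphere radii (nm, positive).
#' @return Logical.
#' @export
sphere_overlap <- function(c1, r1, c2, r2) {
  stopifnot(r1 > 0, r2 > 0)
  sqrt(sum((c1 - c2)^2)) < r1 + r2
}

#' Sample points uniformly inside a sphere
#'
#' @param center Numeric length-3 centre (nm).
#' @param radius Sphere radius (nm, >= 0).
#' @param n Number of points.
#' @return An `n` x 3 matrix of coordinates.
#' @export
sample_point_in_sphere <- function(center, radius, n = 1) {
  stopifnot(radius >= 0)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * runif(n)^(1 / 3)
  sweep(u * r, 2, center, `+`)
}

#' Sample points uniformly in the cytosol
#'
#' Rejection sampling from the ball bounded by the inner membrane surface,
#' keeping only points outside the nucleus, all mitochondria and all
#' nanoparticles.
#'
#' @param geom A `cell_geometry`.
#' @param n Number of points.
#' @param max_attempts Rejection attempts per point before failing.
#' @return An `n` x 3 matrix of coordinates (nm).
#' @export
sample_point_in_cytosol <- function(geom, n = 1, max_attempts = 10000) {
  cpp_sample_cytosol(geom_to_cpp(geom), as.integer(n),
                     as.integer(max_attempts))
}

#' Build the default CHO cell geometry
#'
#' Constructs the spherical CHO cell: a 6000 nm cell with a 10 nm outer
#' membrane shell, a central 3300 nm nucleus, and 90 mitochondria of radius
#' 463 nm placed uniformly at random in the cytosol by rejection sampling
#' (no overlaps, full containment). Deterministic for a fixed RNG seed.
#'
#' @param cell_radius Outer cell radius in nm.
#' @param membrane_thickness Membrane shell thickness in nm.
#' @param nucleus_radius Nucleus radius in nm.
#' @param n_mitochondria Number of mitochondria.
#' @param mitochondrion_radius Mitochondrion radius in nm.
#' @param max_attempts Placement attempts per mitochondrion before failing.
#' @return A validated `cell_geometry`.
#' @export
build_cho_cell <- function(cell_radius = 6000, membrane_thickness = 10,
                           nucleus_radius = 3300, n_mitochondria = 90,
                           mitochondrion_radius = 463, max_attempts = 10000) {
  stopifnot(cell_radius > 0, membrane_thickness > 0,
            membrane_thickness < cell_radius,
            nucleus_radius > 0, n_mitochondria >= 0)
  r_in <- cell_radius - membrane_thickness
  if (nucleus_radius > r_in) {
    abort("nucleus does not fit inside the inner membrane surface")
  }
  spheres <- tibble::tibble(role = "nucleus", id = 1L,
                            x = 0, y = 0, z = 0, radius = nucleus_radius)
  if (n_mitochondria > 0) {
    rm <- mitochondrion_radius
    if (rm <= 0 || nucleus_radius + 2 * rm > r_in) {
      abort("mitochondria do not fit between nucleus and membrane")
    }
    centers <- matrix(NA_real_, n_mitochondria, 3)
    placed <- 0
    for (k in seq_len(n_mitochondria)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- sample_point_in_sphere(c(0, 0, 0), r_in - rm, 1)[1, ]
        d0 <- sqrt(sum(p^2))
        if (d0 < nucleus_radius + rm) next          # overlaps nucleus
        if (placed > 0) {
          dd <- sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                   2, p)^2))
          if (any(dd < 2 * rm)) next                # overlaps a sibling
        }
        centers[k, ] <- p
        placed <- placed + 1
        ok <- TRUE
        break
      }
      if (!ok) {
        abort(sprintf(
          "mitochondrion placement failed after %d attempts (%d of %d placed): cytosol too crowded",
          max_attempts, placed, n_mitochondria))
      }
    }
    spheres <- dplyr::bind_rows(
      spheres,
      tibble::tibble(role = "mitochondrion",
                     id = seq_len(n_mitochondria) + 1L,
                     x = centers[, 1], y = centers[, 2], z = centers[, 3],
                     radius = rm))
  }
  geom <- new_cell_geometry(cell_radius, membrane_thickness, spheres,
                            cho_materials())
  v <- validate_geometry(geom)
  if (nrow(v) > 0) {
    abort(paste0("built geometry fails validation: ", v$message[1]))
  }
  geom
}

#' Nanoparticle placement specification
#'
#' @param n_np Number of nanoparticles (>= 0).
#' @param r_np Nanoparticle radius in nm (> 0).
#' @param fraction_targeted Fraction x in \[0, 1\] of nanoparticles attached
#'   to the target organelle surface; the rest are placed uniformly at random
#'   in the cytosol.
#' @param target Target organelle, `"nucleus"` or `"mitochondria"`.
#' @param max_attempts Placement attempts per nanoparticle before failing.
#' @return A `placement_spec`.
#' @export
placement_spec <- function(n_np, r_np, fraction_targeted = 0,
                           target = c("nucleus", "mitochondria"),
                           max_attempts = 10000) {
  target <- match.arg(target)
  stopifnot(n_np >= 0, r_np > 0,
            fraction_targeted >= 0, fraction_targeted <= 1)
  structure(
    list(n_np = as.integer(n_np), r_np = r_np,
         fraction_targeted = fraction_targeted, target = target,
         max_attempts = as.integer(max_attempts)),
    class = "placement_spec"
  )
}

#' Place gold nanoparticles in a cell geometry
#'
#' `round(n_np * fraction_targeted)` nanoparticles (round-half-even) are
#' attached to the target organelle: their centres sit at distance
#' `R_target + r_np` from the organelle centre, i.e. in direct contact with
#' its surface, with the surface direction drawn uniformly. When the target
#' is the mitochondria, the host mitochondrion is chosen independently and
#' uniformly for each nanoparticle. The remaining nanoparticles are placed
#' uniformly at random in the cytosol. Any placement that overlaps the
#' nucleus, a mitochondrion or a previously placed nanoparticle, or that
#' protrudes through the inner membrane surface, is resampled.
#'
#' @param geom A `cell_geometry`.
#' @param spec A [placement_spec()].
#' @return A new `cell_geometry` with the nanoparticles added.
#' @export
place_nanoparticles <- function(geom, spec) {
  stopifnot(inherits(spec, "placement_spec"))
  if (spec$n_np == 0) return(geom)
  n_targ <- round(spec$n_np * spec$fraction_targeted)
  n_free <- spec$n_np - n_targ
  target_role <- if (spec$target == "nucleus") 3L else 4L
  centers <- cpp_place_nanoparticles(
    geom_to_cpp(geom), as.integer(n_free), as.integer(n_targ), spec$r_np,
    target_role, spec$max_attempts)
  id0 <- if (nrow(geom$spheres) > 0) max(geom$spheres$id) else 0L
  np <- tibble::tibble(role = "nanoparticle",
                       id = id0 + seq_len(nrow(centers)),
                       x = centers[, 1], y = centers[, 2], z = centers[, 3],
                       radius = spec$r_np)
  geom$spheres <- dplyr::bind_rows(geom$spheres, np)
  geom
}

#' Classify points by cell region
#'
#' Containment precedence: nanoparticle > mitochondrion > nucleus > membrane
#' shell > cytosol > outside; points within 1e-9 nm of a boundary belong to
#' the inner (more specific) region.
#'
#' @param geom A `cell_geometry`.
#' @param points Numeric length-3 vector or an n x 3 matrix (nm).
#' @return Character vector of region roles.
#' @export
region_at <- function(geom, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  codes <- cpp_region_at(geom_to_cpp(geom), points)
  region_code_to_role(codes)
}

#' Trace a ray through the cell geometry
#'
#' Splits a ray into contiguous segments at every sphere-surface crossing,
#' computed from analytic ray-sphere intersections. Segments are labelled by
#' the region of their midpoint and stop at the cell exit or after
#' `max_length`, whichever comes first.
#'
#' @param geom A `cell_geometry`.
#' @param origin Numeric length-3 start point (nm).
#' @param direction Unit direction vector (|direction| = 1 within 1e-9).
#' @param max_length Maximum traced length in nm (default unbounded).
#' @return Tibble with columns `region`, `entry_x`, `entry_y`, `entry_z`,
#'   `length`. An origin outside the cell yields a single `outside` segment.
#' @export
trace_path <- function(geom, origin, direction, max_length = Inf) {
  m <- cpp_trace_path(geom_to_cpp(geom), as.numeric(origin),
                      as.numeric(direction), max_length)
  tibble::tibble(
    region = region_code_to_role(as.integer(m[, 1])),
    entry_x = m[, 2], entry_y = m[, 3], entry_z = m[, 4],
    length = m[, 5]
  )
}

#' Gold mass percentage of a nanoparticle loading
#'
#' Mass of gold in the nanoparticles relative to the mass of the whole cell
#' sphere at 1.0 g/cm^3, in percent:
#' `100 * n_np * r_np^3 * rho_Au / (R_cell^3 * rho_cell)`.
#'
#' @param spec A [placement_spec()].
#' @param geom A `cell_geometry`.
#' @return Gold mass percentage of the cell.
#' @export
gold_mass_percent <- function(spec, geom) {
  rho_au <- gold_material()$density
  100 * spec$n_np * spec$r_np^3 * rho_au / (geom$cell_radius^3 * 1.0)
}

#' Validate a cell geometry
#'
#' Checks every invariant analytically: positive radii, containment of the
#' nucleus, mitochondria and nanoparticles inside the inner membrane surface,
#' and pairwise non-overlap among all of them (tangency allowed, tolerance
#' 1e-9 nm).
#'
#' @param geom A `cell_geometry`.
#' @return Tibble of violations with columns `rule`, `id1`, `id2`,
#'   `message`; zero rows means the geometry is valid.
#' @export
validate_geometry <- function(geom) {
  sp <- geom$spheres
  out <- list()
  tol <- 1e-9
  r_in <- inner_radius(geom)
  if (geom$membrane_thickness <= 0 || r_in <= 0) {
    out[[length(out) + 1]] <- tibble::tibble(
      rule = "membrane", id1 = NA_integer_, id2 = NA_integer_,
      message = "membrane outer radius must exceed inner radius")
  }
  if (nrow(sp) > 0) {
    bad_r <- which(sp$radius <= 0)
    for (i in bad_r) {
      out[[length(out) + 1]] <- tibble::tibble(
        rule = "radius", id1 = sp$id[i], id2 = NA_integer_,
        message = sprintf("sphere %d has non-positive radius", sp$id[i]))
    }
    d0 <- sqrt(sp$x^2 + sp$y^2 + sp$z^2)
    uncontained <- which(d0 + sp$radius > r_in + tol)
    for (i in uncontained) {
      out[[length(out) + 1]] <- tibble::tibble(
        rule = "containment", id1 = sp$id[i], id2 = NA_integer_,
        message = sprintf(
          "%s %d protrudes beyond the inner membrane surface (reach %.6g > %.6g nm)",
          sp$role[i], sp$id[i], d0[i] + sp$radius[i], r_in))
    }
    pairs <- cpp_overlap_pairs(cbind(sp$x, sp$y, sp$z), sp$radius, tol)
    if (nrow(pairs) > 0) {
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1] + 1L
        j <- pairs[k, 2] + 1L
        out[[length(out) + 1]] <- tibble::tibble(
          rule = "overlap", id1 = sp$id[i], id2 = sp$id[j],
          message = sprintf("%s %d overlaps %s %d",
                            sp$role[i], sp$id[i], sp$role[j], sp$id[j]))
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(rule = character(), id1 = integer(), id2 = integer(),
                   message = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Write a geometry as a CSV table
#'
#' One sphere per row with columns role, id, x, y, z, radius (nm).
#'
#' @param geom A `cell_geometry`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_geometry_csv <- function(geom, path) {
  write.csv(geom$spheres, path, row.names = FALSE)
  invisible(path)
}
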