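# Small geometries and oracles shared across the test files.

# cell with nucleus only (no mitochondria), default CHO dimensions
nucleus_only_cell <- function() {
  cell_geometry(6000, 10, nucleus_radius = 3300)
}

# organelle-free water ball with membrane shell
bare_cell <- function(cell_radius = 6000, membrane_thickness = 10) {
  cell_geometry(cell_radius, membrane_thickness)
}

# brute-force region classifier used as the independent oracle for
# region_at(): test every sphere, innermost/most-specific role wins
brute_force_region <- function(geom, pts) {
  tol <- 1e-9
  r_in <- inner_radius(geom)
  sp <- as_tibble(geom)
  apply(pts, 1, function(p) {
    d0 <- sqrt(sum(p^2))
    if (d0 > geom$cell_radius + tol) return("outside")
    d <- sqrt((sp$x - p[1])^2 + (sp$y - p[2])^2 + (sp$z - p[3])^2)
    inside <- d <= sp$radius + tol
    for (role in c("nanoparticle", "mitochondrion", "nucleus")) {
      if (any(inside & sp$role == role)) return(role)
    }
    if (d0 > r_in + tol) return("membrane")
    "cytosol"
  })
}

# kinetic energy left after an electron travels path length `len_nm`
# straight through water, by inverting the CSDA range integral
energy_after_path <- function(e0_kev, len_nm, mat = water_material(),
                              cutoff = 1) {
  r0 <- csda_range(e0_kev, mat, cutoff) * 1e6  # nm
  if (len_nm >= r0) return(0)
  target <- r0 - len_nm
  stats::uniroot(function(e) csda_range(e, mat, cutoff) * 1e6 - target,
                 c(cutoff, e0_kev), tol = 1e-10)$root
}

# cached water range table (nm) for fast interpolation in oracle code
water_range_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      e <- exp(seq(log(1), log(1000), length.out = 400))
      tab <<- list(loge = log(e),
                   r = csda_range(e, water_material()) * 1e6)
    }
    tab
  }
})

# interpolated version of energy_after_path for bulk oracle evaluations
energy_after_path_fast <- function(e0_kev, len_nm) {
  tab <- water_range_table()
  r0 <- stats::approx(tab$loge, tab$r, log(e0_kev))$y
  target <- r0 - len_nm
  if (target <= 0) return(0)
  exp(stats::approx(tab$r, tab$loge, target)$y)
}
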