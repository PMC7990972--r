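test_that("default CHO build places 90 valid mitochondria, reproducibly", {
  set.seed(42)
  g <- build_cho_cell()
  sp <- as_tibble(g)
  expect_equal(sum(sp$role == "mitochondrion"), 90)
  expect_equal(nrow(validate_geometry(g)), 0)
  set.seed(42)
  g2 <- build_cho_cell()
  expect_identical(as_tibble(g), as_tibble(g2))
})

test_that("degenerate build parameters are handled", {
  set.seed(1)
  g <- build_cho_cell(n_mitochondria = 0)
  expect_equal(sum(as_tibble(g)$role == "mitochondrion"), 0)
  expect_equal(nrow(validate_geometry(g)), 0)
  expect_error(build_cho_cell(nucleus_radius = 6001, cell_radius = 6000),
               "nucleus")
})

test_that("sphere overlap is strict so tangency is allowed", {
  expect_true(sphere_overlap(c(0, 0, 0), 5, c(0, 0, 0), 5))
  expect_false(sphere_overlap(c(0, 0, 0), 3, c(5, 0, 0), 2))
  # a surface-attached nanoparticle is legal
  expect_false(sphere_overlap(c(0, 0, 0), 3300, c(3305, 0, 0), 5))
  expect_true(sphere_overlap(c(0, 0, 0), 3300, c(3304.999, 0, 0), 5))
})

test_that("points sampled in a sphere are volume-uniform", {
  set.seed(7)
  n <- 1e5
  p <- sample_point_in_sphere(c(0, 0, 0), 1, n)
  r3 <- rowSums(p^2)^1.5
  # r^3 of a uniform ball point is U(0,1): mean 1/2, var 1/12
  expect_lt(abs(mean(r3) - 0.5), 3 * sqrt(1 / 12 / n))
  # centred by symmetry; per-coordinate variance R^2/5
  for (j in 1:3) expect_lt(abs(mean(p[, j])), 3 * sqrt(0.2 / n))
  expect_equal(sample_point_in_sphere(c(1, 2, 3), 0, 1)[1, ], c(1, 2, 3))
})

test_that("cytosol sampling is uniform over the cytosol only", {
  set.seed(8)
  g <- nucleus_only_cell()
  n <- 1e4
  p <- sample_point_in_cytosol(g, n)
  expect_true(all(region_at(g, p) == "cytosol"))
  # radial shell fraction matches the analytic volume ratio
  r <- sqrt(rowSums(p^2))
  frac <- mean(r >= 3300 & r <= 4000)
  expected <- (4000^3 - 3300^3) / (5990^3 - 3300^3)
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n))
  # organelle-free cell: uniform in the inner ball
  set.seed(9)
  pb <- sample_point_in_cytosol(bare_cell(), n)
  expect_true(all(sqrt(rowSums(pb^2)) <= 5990))
})

test_that("nucleus-targeted nanoparticles sit exactly on the surface", {
  set.seed(10)
  g <- nucleus_only_cell()
  gt <- place_nanoparticles(g, placement_spec(1000, 5, fraction_targeted = 1))
  np <- dplyr::filter(as_tibble(gt), role == "nanoparticle")
  expect_equal(nrow(np), 1000)
  d <- sqrt(np$x^2 + np$y^2 + np$z^2)
  expect_true(all(abs(d - 3305) < 1e-6))
  # isotropic on the surface: mean position at the nucleus centre
  se <- 3305 / sqrt(3 * nrow(np))
  expect_lt(abs(mean(np$x)), 3 * se)
  expect_lt(abs(mean(np$y)), 3 * se)
  expect_lt(abs(mean(np$z)), 3 * se)
  expect_equal(nrow(validate_geometry(gt)), 0)
})

test_that("empty placement leaves the geometry unchanged", {
  g <- nucleus_only_cell()
  expect_identical(place_nanoparticles(g, placement_spec(0, 5)), g)
})

test_that("mixed placement respects all invariants and host choice", {
  set.seed(11)
  g <- build_cho_cell(n_mitochondria = 20)
  gm <- place_nanoparticles(
    g, placement_spec(500, 5, fraction_targeted = 0.5,
                      target = "mitochondria"))
  expect_equal(nrow(validate_geometry(gm)), 0)
  np <- dplyr::filter(as_tibble(gm), role == "nanoparticle")
  expect_equal(nrow(np), 500)
  # the targeted half touch some mitochondrion surface (distance 463 + 5)
  mito <- dplyr::filter(as_tibble(gm), role == "mitochondrion")
  dmin <- vapply(seq_len(nrow(np)), function(i) {
    min(sqrt((mito$x - np$x[i])^2 + (mito$y - np$y[i])^2 +
               (mito$z - np$z[i])^2))
  }, numeric(1))
  expect_equal(sum(abs(dmin - 468) < 1e-6), 250)
})

test_that("region classification matches the brute-force oracle", {
  set.seed(12)
  g <- build_cho_cell(n_mitochondria = 8)
  g <- place_nanoparticles(g, placement_spec(10, 50, fraction_targeted = 0.5))
  expect_lte(nrow(as_tibble(g)), 20)
  pts <- matrix(runif(3e5, -6100, 6100), ncol = 3)
  expect_identical(region_at(g, pts), brute_force_region(g, pts))
  # spot conventions
  expect_equal(region_at(g, c(0, 0, 0)), "nucleus")
  expect_equal(region_at(g, c(5995, 0, 0)), "membrane")
  expect_equal(region_at(g, c(7000, 0, 0)), "outside")
})

test_that("ray tracing yields analytic chord lengths", {
  tp <- trace_path(bare_cell(), c(0, 0, 0), c(1, 0, 0))
  expect_equal(tp$region, c("cytosol", "membrane"))
  expect_equal(tp$length, c(5990, 10))
  tp2 <- trace_path(nucleus_only_cell(), c(5000, 0, 0), c(-1, 0, 0))
  expect_equal(tp2$region, c("cytosol", "nucleus", "cytosol", "membrane"))
  expect_equal(tp2$length, c(1700, 6600, 2690, 10))
  out <- trace_path(bare_cell(), c(9000, 0, 0), c(1, 0, 0))
  expect_equal(out$region, "outside")
})

test_that("traced segment lengths sum to the ray length to the cell exit", {
  set.seed(13)
  g <- build_cho_cell(n_mitochondria = 30)
  g <- place_nanoparticles(g, placement_spec(100, 5, fraction_targeted = 0.3))
  for (k in 1:50) {
    o <- sample_point_in_sphere(c(0, 0, 0), 5500, 1)[1, ]
    d <- as.vector(sample_point_in_sphere(c(0, 0, 0), 1, 1))
    d <- d / sqrt(sum(d^2))
    tp <- trace_path(g, o, d)
    # analytic distance from o to the cell sphere along d
    b <- sum(o * d)
    texit <- -b + sqrt(b^2 - (sum(o^2) - 6000^2))
    expect_lt(abs(sum(tp$length) - texit), 1e-8)
  }
})

test_that("gold mass percentages reproduce the tabulated loadings", {
  g <- nucleus_only_cell()
  expect_equal(signif(gold_mass_percent(placement_spec(1e4, 5), g), 2),
               1.1e-2)
  expect_equal(signif(gold_mass_percent(placement_spec(1e4, 3), g), 2),
               2.4e-3)
  expect_equal(signif(gold_mass_percent(placement_spec(1e4, 4), g), 2),
               5.7e-3)
  expect_equal(gold_mass_percent(placement_spec(0, 5), g), 0)
})

test_that("validation reports overlaps and containment violations", {
  g <- nucleus_only_cell()
  g$spheres <- dplyr::bind_rows(
    g$spheres,
    tibble::tibble(role = "nanoparticle", id = c(2L, 3L, 4L),
                   x = c(4000, 4000, 5999), y = 0, z = 0,
                   radius = 5))
  v <- validate_geometry(g)
  expect_equal(sum(v$rule == "overlap"), 1)
  expect_equal(sum(v$rule == "containment"), 1)
  expect_true(any(grepl("nanoparticle 4", v$message)))
})

test_that("TOPAS parameter export round-trips the geometry", {
  set.seed(14)
  g <- build_cho_cell()
  spec <- placement_spec(100, 5, fraction_targeted = 1)
  g2 <- place_nanoparticles(g, spec)
  lines <- export_topas_parameters(g2, spec)
  p <- parse_topas_parameters(lines)
  expect_identical(p[["Nucleus/NucleusRadius"]], 3300)
  expect_identical(p[["CellRadius"]], 6000)
  expect_identical(p[["Mitochondria/Radius"]], 463)
  expect_identical(p[["Nanoparticle/Radius"]], 5)
  expect_identical(p[["Nanoparticle/Target"]], "nucleus")
  # no nanoparticle block without nanoparticles
  lines0 <- export_topas_parameters(g)
  expect_false(any(grepl("Nanoparticle", lines0)))
  # file round trip
  f <- tempfile(fileext = ".txt")
  export_topas_parameters(g2, spec, path = f)
  expect_identical(parse_topas_parameters(f)[["CellRadius"]], 6000)
  unlink(f)
})

test_that("cytosol-placed nanoparticles are volume-uniform over radial shells", {
  set.seed(15)
  g <- nucleus_only_cell()
  gp <- place_nanoparticles(g, placement_spec(1e4, 5))
  np <- dplyr::filter(as_tibble(gp), role == "nanoparticle")
  r <- sqrt(np$x^2 + np$y^2 + np$z^2)
  lo <- 3300 + 5
  hi <- 5990 - 5
  breaks <- (seq(lo^3, hi^3, length.out = 11))^(1 / 3)  # equal sub-volumes
  counts <- table(cut(r, breaks, include.lowest = TRUE))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})
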