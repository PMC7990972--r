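fake_tally <- function(cell_ev, n_decays = 1) {
  structure(
    list(n_decays = n_decays,
         energy_ev = c(membrane = 0, cytosol = cell_ev, nucleus = 0,
                       mitochondrion = 0, nanoparticle = 0),
         escaped_ev = 0, emitted_ev = cell_ev, mode = "continuous",
         gold_mass_percent = 0),
    class = "energy_tally"
  )
}

test_that("batch summaries use the sample standard deviation", {
  same <- replicate(10, fake_tally(5), simplify = FALSE)
  s <- summarize_batches(same)
  expect_true(all(s$sd_ev_per_decay == 0))
  b <- lapply(c(1, 2, 3), fake_tally)
  s2 <- summarize_batches(b)
  row <- s2[s2$region == "cell", ]
  expect_equal(unname(row$mean_ev_per_decay), 2)
  expect_equal(unname(row$sd_ev_per_decay), 1)
  # mean invariant under permutation
  s3 <- summarize_batches(b[c(3, 1, 2)])
  expect_equal(s2$mean_ev_per_decay, s3$mean_ev_per_decay)
  # single batch: sd absent
  expect_true(is.na(summarize_batches(b[1])$sd_ev_per_decay[1]))
})

test_that("dose conversion reproduces the 32-35 Gy whole-cell dose", {
  g <- nucleus_only_cell()
  m <- cell_mass_kg(g)
  expect_equal(m, 4 / 3 * pi * (6e-4)^3 * 1e-3, tolerance = 1e-12)
  d_cont <- dose_gy(1810 * 1e5, m)
  d_disc <- dose_gy(1913 * 1e5, m)
  expect_gte(d_cont, 32)
  expect_lte(d_disc, 35)
  expect_equal(dose_gy(0, m), 0)
  expect_equal(dose_gy(2 * 1810 * 1e5, m), 2 * d_cont)
  expect_error(dose_gy(1, 0), "positive")
})

test_that("relative enhancement is 100% at baseline and errors on zero", {
  rich <- function(scale) {
    t <- fake_tally(1)
    t$energy_ev <- scale * c(membrane = 1, cytosol = 2, nucleus = 3,
                             mitochondrion = 4, nanoparticle = 5)
    t
  }
  b <- summarize_batches(lapply(c(1, 2, 3), rich))
  expect_true(all(relative_enhancement(b, b)$e_rel_percent == 100))
  zero <- summarize_batches(list(fake_tally(0)))
  expect_error(relative_enhancement(b, zero), "positive")
})

test_that("linearity fits recover exact lines and degenerate cases", {
  x <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  f <- linearity_fit(x, 2 + 3 * x)
  expect_equal(f$slope, 3)
  expect_equal(f$intercept, 2)
  expect_equal(f$r_squared, 1)
  # constant response: slope 0, R^2 defined as 1 when SS_tot = 0
  f0 <- linearity_fit(x, rep(5, 6))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 1)
  expect_error(linearity_fit(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("summaries, enhancement and plots compose on real batches", {
  set.seed(50)
  g <- place_nanoparticles(nucleus_only_cell(), placement_spec(100, 5))
  b <- run_batches(g, 300, 3, base_seed = 51, mode = "discrete")
  s <- summarize_batches(b)
  expect_setequal(
    s$region,
    c("cell", "cytosol", "cytosol_no_np", "nucleus", "mitochondria",
      "membrane", "nanoparticles"))
  # Table-1 convention: cytosol column includes the nanoparticle deposit
  expect_equal(unname(s$mean_ev_per_decay[s$region == "cytosol"]),
               unname(s$mean_ev_per_decay[s$region == "cytosol_no_np"] +
                        s$mean_ev_per_decay[s$region == "nanoparticles"]))
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
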