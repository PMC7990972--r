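small_config <- function(dir, ...) {
  cfg <- read_run_config(NULL)
  cfg$n_decays <- 400
  cfg$n_batches <- 2
  cfg$n_np <- 200
  cfg$n_mitochondria <- 20
  cfg$x_values <- c(0, 0.5, 1)
  cfg$base_seed <- 7
  cfg$output_dir <- dir
  extra <- list(...)
  for (k in names(extra)) cfg[[k]] <- extra[[k]]
  validate_run_config(cfg)
  cfg
}

test_that("config files parse, validate and reject unknown keys", {
  f <- tempfile()
  writeLines(c("# comment", "n_decays = 1234", "target = mitochondria",
               "multiple_scattering = false",
               "x_values = 0, 0.5, 1"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$n_decays, 1234)
  expect_equal(cfg$target, "mitochondria")
  expect_false(cfg$multiple_scattering)
  expect_equal(cfg$x_values, c(0, 0.5, 1))
  writeLines("no_such_key = 1", f)
  err <- tryCatch(read_run_config(f), condition = function(e) e)
  expect_s3_class(err, "celldosim_config_error")
  expect_match(conditionMessage(err), "no_such_key")
  writeLines("n_decays = banana", f)
  expect_error(read_run_config(f), "expects a number")
  unlink(f)
})

test_that("the targeting sweep experiment emits baseline-normalised outputs", {
  dir <- tempfile()
  cfg <- small_config(dir)
  res <- run_experiment(cfg)
  expect_true(file.exists(file.path(dir, "summary.csv")))
  expect_true(file.exists(file.path(dir, "enhancement.csv")))
  expect_true(file.exists(file.path(dir, "manifest.txt")))
  enh <- read.csv(file.path(dir, "enhancement.csv"))
  base <- enh[enh$x == 0, ]
  expect_true(all(abs(base$e_rel_percent - 100) < 1e-9))
  unlink(dir, recursive = TRUE)
})

test_that("re-running the same config or its manifest is bitwise identical", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  cfg <- small_config(d1, x_values = c(0, 1), n_decays = 200)
  run_experiment(cfg)
  cfg$output_dir <- d2
  run_experiment(cfg)
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  # manifest round trip
  m <- read_run_config(file.path(d1, "manifest.txt"))
  m$output_dir <- d3
  run_experiment(m)
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d3, "summary.csv")))
  expect_identical(readLines(file.path(d1, "enhancement.csv")),
                   readLines(file.path(d3, "enhancement.csv")))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("the mass-independence sweep spans the documented gold loadings", {
  dir <- tempfile()
  cfg <- small_config(dir, experiment = "mass_independence",
                      n_decays = 150, n_batches = 1)
  res <- run_experiment(cfg)
  enh <- res$enhancement
  expect_equal(signif(min(enh$m_aunp_percent), 2), 2.4e-3)
  expect_equal(signif(max(enh$m_aunp_percent), 2), 4.5e-2)
  expect_equal(length(unique(enh$m_aunp_percent)), 5)
  unlink(dir, recursive = TRUE)
})

test_that("the continuous sweep covers four gold mass percentages", {
  dir <- tempfile()
  cfg <- small_config(dir, experiment = "continuous_sweep", n_decays = 150,
                      n_batches = 1)
  res <- run_experiment(cfg)
  expect_setequal(unique(res$summary$gold_mass_percent),
                  c(0.001, 0.01, 0.1, 1))
  unlink(dir, recursive = TRUE)
})

test_that("the command line interface reports status codes", {
  dir <- tempfile()
  f <- tempfile()
  writeLines(c("n_mitochondria = 5", "n_decays = 50"), f)
  expect_equal(run_cli(c("build-geometry", "--config", f, "--out", dir)),
               0L)
  expect_true(file.exists(file.path(dir, "geometry.csv")))
  expect_true(file.exists(file.path(dir, "geometry.topas.txt")))
  expect_equal(suppressMessages(run_cli(c("frobnicate"))), 1L)
  expect_equal(suppressMessages(run_cli(c("run", "--config",
                                          "/no/such/file"))), 1L)
  writeLines("bogus_key = 1", f)
  expect_equal(suppressMessages(run_cli(c("run", "--config", f))), 1L)
  unlink(c(f, dir), recursive = TRUE)
})
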