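make_fixture <- function(n = 10, seed = 4, dir = tempfile("icp")) {
  dir.create(dir)
  # event-rich configuration so that small fixtures stay non-degenerate
  cfg <- sim_config(n = n, k01 = c(0.25, 0.4), b01 = c(0.8, 0.7))
  recs <- observed_records(draw_dataset(cfg, seed))
  path <- file.path(dir, "records.csv")
  write_subject_records(recs, path)
  list(dir = dir, records = recs, path = path)
}

test_that("subject records round-trip through delimited text", {
  fx <- make_fixture(n = 25)
  back <- read_subject_records(fx$path)
  expect_equal(as.data.frame(back), as.data.frame(fx$records),
               tolerance = 1e-12)
  # missing l1 for exact events is filled with t1 on read
  txt <- "id,l1,t1,d1,exact,t2,d2\n1,NA,2,1,1,3,0\n2,3,3,0,1,3,1\n"
  f <- file.path(fx$dir, "na.csv")
  writeLines(txt, f)
  r <- read_subject_records(f)
  expect_equal(r$l1[1], 2)
})

test_that("cli_fit writes a model file and is byte-identical on reruns", {
  fx <- make_fixture(n = 30, seed = 10)
  cfg <- list(input = fx$path, output_dir = file.path(fx$dir, "out"),
              eval_times = 3, knots = list(m = 0), nodes = 64L, seed = 1L,
              link = "identity", covariates = NULL)
  p1 <- cli_fit(cfg)
  expect_true(file.exists(p1))
  m <- read_idm(p1)
  expect_s3_class(m, "illness_death_model")
  bytes1 <- readBin(p1, "raw", file.size(p1))
  unlink(cfg$output_dir, recursive = TRUE)
  p2 <- cli_fit(cfg)              # identical config: byte-identical output
  bytes2 <- readBin(p2, "raw", file.size(p2))
  expect_identical(bytes1, bytes2)
})

test_that("cli_fit reports schema violations with the offending row", {
  d <- tempfile("bad"); dir.create(d)
  f <- file.path(d, "bad.csv")
  writeLines("id,l1,t1,d1,exact,t2,d2\n1,2,2,1,1,3,0\n2,2.5,2,1,0,3,0", f)
  cfg <- list(input = f, output_dir = d, knots = list(m = 0), nodes = 64L,
              seed = 1L)
  expect_error(cli_fit(cfg), "row 2")
})

test_that("cli_pseudo writes one row per subject and time and is deterministic", {
  fx <- make_fixture(n = 20, seed = 12)
  cfg <- list(input = fx$path, output_dir = file.path(fx$dir, "ps"),
              eval_times = c(2, 3), knots = list(m = 0), nodes = 64L,
              seed = 1L)
  p <- cli_pseudo(cfg)
  tab <- read_pseudo_table(p)
  expect_equal(nrow(tab), 20L * 2L)
  expect_named(tab, c("id", "time", "pseudo", "converged"))
  cfg$output_dir <- file.path(fx$dir, "ps2")
  p2 <- cli_pseudo(cfg)
  expect_identical(readLines(p), readLines(p2))
  # evaluation beyond follow-up warns about extrapolation
  cfg$eval_times <- 50
  cfg$output_dir <- file.path(fx$dir, "ps3")
  expect_warning(cli_pseudo(cfg), "extrapolat")
})

test_that("cli_regress reproduces closed-form GEE solutions", {
  fx <- make_fixture(n = 40, seed = 3)
  ps <- pseudo_obs(fx$records, eval_times = 3, specs = m0_specs())
  ptab <- file.path(fx$dir, "pseudo.csv")
  write_pseudo_table(ps, ptab)
  out <- file.path(fx$dir, "reg")
  # intercept-only: estimate is the mean pseudo-value
  cfg <- list(pseudo_table = ptab, output_dir = out, link = "identity",
              covariates = NULL, seed = 1L)
  res <- read.csv(cli_regress(cfg))
  expect_equal(res$estimate[res$quantity == "risk"], mean(ps$pseudo),
               tolerance = 1e-10)
  # binary covariate: risk difference equals the group mean difference
  cfg$covariates <- "x"
  cfg$covariate_file <- fx$path
  cfg$output_dir <- file.path(fx$dir, "reg2")
  res2 <- read.csv(cli_regress(cfg))
  z <- fx$records$x
  expect_equal(res2$estimate[res2$quantity == "risk_difference"],
               mean(ps$pseudo[z == 1]) - mean(ps$pseudo[z == 0]),
               tolerance = 1e-10)
  # unknown link is a usage error
  cfg$link <- "cloglog"
  expect_error(cli_regress(cfg), "unknown link")
})

test_that("cli_simulate and cli_study write coherent outputs", {
  d <- tempfile("sim"); dir.create(d)
  cfg <- list(sim = list(n = 40, m = 0), seed = 6L, output_dir = d,
              reps = 2L, methods = "ic")
  p <- cli_simulate(cfg)
  recs <- read_subject_records(p)
  expect_equal(nrow(recs), 40L)
  ps <- cli_study(cfg)
  met <- read.csv(ps)
  expect_true(all(c("method", "estimand", "empSE", "coverage") %in% names(met)))
})

test_that("yaml configs are read with defaults filled in", {
  f <- tempfile(fileext = ".yaml")
  writeLines("input: records.csv\nknots:\n  m: 2\nsim:\n  n: 99", f)
  cfg <- read_run_config(f)
  expect_equal(cfg$knots$m, 2L)
  expect_equal(cfg$sim$n, 99L)
  expect_equal(cfg$eval_times, 3)
  expect_equal(cfg$nodes, 64L)
  expect_error(cli_main(c("nope", f)), "usage")
})
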