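test_that("config validation is strict: unknown keys and bad bounds error", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))
  bad <- cfg
  bad$typo_key <- 1
  expect_error(validate_config(bad), "unknown config key")
  bad <- cfg
  bad$gc$not_a_knob <- 2
  expect_error(validate_config(bad), "unknown config key")
  bad <- cfg
  bad$working_range$kd_min <- 1e-2
  expect_error(validate_config(bad), "out of order")
  bad <- cfg
  bad$germline$kd_min <- 1
  expect_error(validate_config(bad), "out of order")
  bad <- cfg
  bad$n_steps <- -1
  expect_error(validate_config(bad), "n_steps")
  bad <- cfg
  bad$schema_version <- "99"
  expect_error(validate_config(bad), "schema_version")
})

test_that("config files round-trip with defaults filled and unknown keys rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  write_config(list(schema_version = "1", seed = 7, n_steps = 3), path)
  cfg <- read_config(path)
  expect_identical(cfg$seed, 7L)
  expect_identical(cfg$n_steps, 3L)
  expect_equal(cfg$blood$volume, 5.0) # defaults resolved at load, not run time
  bad <- withr::local_tempfile(fileext = ".json")
  write_config(list(schema_version = "1", seeed = 7), bad)
  expect_error(read_config(bad), "unknown config key")
  expect_error(read_config("/nonexistent/cfg.json"), "not found")
})

test_that("a zero-step simulation leaves founders untouched", {
  cfg <- default_config(seed = 5, n_steps = 0)
  res <- simulate(cfg)
  expect_identical(nrow(res$trajectory), 0L)
  expect_length(res$clones, cfg$clones$n_founders)
  expect_true(all(vapply(res$clones, `[[`, "", "stage") == "IMMATURE"))
})

test_that("single blood clone in the B1 band persists with constant antigen", {
  cfg <- default_config(seed = 2, n_steps = 100)
  cfg$clones$n_founders <- 1L
  cfg$clones$start_niche <- "BLOOD"
  res <- simulate(cfg)
  tr <- res$trajectory
  expect_identical(tr$action[1], "PERSIST_G1:B1") # seed chosen in the B1 band
  expect_length(res$clones, 1)
  expect_identical(res$clones[[1]]$stage, "B1")
  # inexhaustible pool: free antigen bit-identical at every step
  expect_length(unique(tr$ag_free), 1L)
  expect_true(all(tr$n_cells >= 1 &
                    tr$n_cells <= cfg$agents$population_cap))
  # B1 cadence: persists in G1, dividing from time to time
  expect_true(all(tr$action %in% c("PERSIST_G1:B1", "PERSIST_G1", "DIVIDE")))
  expect_gt(sum(tr$action == "DIVIDE"), 0)
})

test_that("no emitted record carries a kd outside the working range", {
  for (s in c(1, 9)) {
    cfg <- default_config(seed = s, n_steps = 40)
    tr <- simulate(cfg)$trajectory
    if (!nrow(tr)) next
    expect_true(all(tr$kd_apparent > 0))
    kd_intr <- tr$kd_apparent # apparent can only differ by the factor
    expect_true(all(tr$kd_apparent >= 1e-14 / 1e3 &
                      tr$kd_apparent <= 1e-3 * 1e3))
    # occupancy consistent with (ag_free, kd_apparent)
    expect_equal(tr$occupancy, tr$ag_free / (tr$ag_free + tr$kd_apparent),
                 tolerance = 1e-9)
  }
})

test_that("phase map has a contiguous diagonal comfort band and ordered rows", {
  band <- engagement_band()
  g <- decade_grid(1e-14, 1e-3, per_decade = 2)
  m <- phase_map(g, g, band)
  expect_identical(dim(m), c(length(g), length(g)))
  # every diagonal cell (ag == kd) is COMFORT
  expect_true(all(diag(m) == "COMFORT"))
  expect_identical(m[length(g), 1], "SATURATED") # ag=1e-3, kd=1e-14
  expect_identical(m[1, length(g)], "NEGLECT")   # ag=1e-14, kd=1e-3
  ord <- stats::setNames(seq_along(bcrsim:::ENGAGEMENT_LEVELS),
                         bcrsim:::ENGAGEMENT_LEVELS)
  idx <- matrix(ord[m], nrow(m))
  # moving to higher ag at fixed kd never decreases the class
  expect_true(all(apply(idx, 2, function(col) all(diff(col) >= 0))))
  # moving to higher kd at fixed ag never increases the class
  expect_true(all(apply(idx, 1, function(row) all(diff(row) <= 0))))
  # comfort cells form one contiguous run in every column that has any
  runs <- apply(idx, 2, function(col) {
    r <- rle(col == ord[["COMFORT"]])
    sum(r$values)
  })
  expect_true(all(runs <= 1))
  expect_error(phase_map(numeric(0), g), "non-empty")
})

test_that("outputs round-trip and empty trajectories still write a header", {
  cfg <- default_config(seed = 4, n_steps = 15)
  res <- simulate(cfg)
  dir <- withr::local_tempdir()
  files <- write_outputs(res$trajectory, res$summary, dir)
  back <- read_trajectory(files[["trajectory"]])
  expect_identical(nrow(back), nrow(res$trajectory))
  expect_identical(back$clone_id, res$trajectory$clone_id)
  expect_equal(back$ag_free, res$trajectory$ag_free, tolerance = 1e-8)
  # 9-significant-digit scientific notation by contract
  line2 <- readLines(files[["trajectory"]], n = 2)[2]
  expect_match(line2, "\\d\\.\\d{8}e[+-]\\d{2}")
  dir2 <- withr::local_tempdir()
  empty <- write_outputs(res$trajectory[0, ], res$summary, dir2)
  expect_identical(readLines(empty[["trajectory"]]),
                   "step,niche,clone_id,stage,n_cells,kd_apparent,occupancy,ag_free,action")
})

test_that("the CLI runs its subcommands and signals validation errors", {
  out <- withr::local_tempdir()
  cfgf <- file.path(out, "cfg.json")
  write_config(list(schema_version = "1", n_steps = 5), cfgf)
  status <- suppressMessages(
    bcrsim_cli(c("simulate", "--config", cfgf, "--seed", "3", "--out", out)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  pm <- file.path(out, "pm.tsv")
  status <- suppressMessages(
    bcrsim_cli(c("phase-map", "--band", "0.5", "--grid", "12", "--out", pm)))
  expect_identical(status, 0L)
  expect_identical(dim(as.matrix(utils::read.table(pm, sep = "\t",
                                                   row.names = 1,
                                                   header = TRUE))),
                   c(12L, 12L))
  # bad config -> status 2, no crash
  badf <- file.path(out, "bad.json")
  writeLines('{"schema_version": "1", "nonsense": true}', badf)
  status <- suppressMessages(
    bcrsim_cli(c("simulate", "--config", badf, "--out", out)))
  expect_identical(status, 2L)
  status <- suppressMessages(bcrsim_cli("frobnicate"))
  expect_identical(status, 2L)
})

test_that("the gc subcommand writes a pooled ensemble summary", {
  out <- withr::local_tempdir()
  cfgf <- file.path(out, "cfg.json")
  # scaled-down schedule to keep the CLI test fast
  write_config(list(schema_version = "1", seed = 1,
                    gc = list(max_cycles = 5, founder_n = 6, n_doses = 1)),
               cfgf)
  status <- suppressMessages(
    bcrsim_cli(c("gc", "--config", cfgf, "--seeds", "2", "--out", out)))
  expect_identical(status, 0L)
  s <- jsonlite::read_json(file.path(out, "gc_summary.json"),
                           simplifyVector = TRUE)
  expect_identical(s$n_seeds, 2L)
  expect_gt(s$n_clones, 0)
  cl <- utils::read.csv(file.path(out, "gc_clones.csv"))
  expect_identical(nrow(cl), s$n_clones)
})
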