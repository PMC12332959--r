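# Configuration handling and the simulate / decode / report pipeline.

small_config <- function(seed = 5L) {
  cfg <- default_config(seed = seed, preset = "two_population")
  cfg$simulate$groups <- data.frame(
    area = c("TE", "TEO"), experience = "object_task",
    n_cells = c(8L, 6L), alpha_mean = c(0.8, 0.1), animal = "simA")
  cfg$simulate$n_trials_per_image <- 12L
  cfg$analysis$n_pseudo_trials <- 10L
  cfg$analysis$range_ms <- c(-150, 350)
  cfg$analysis$deltas <- c(30L)
  cfg
}

test_that("configs validate and errors name the offending key", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))
  bad <- cfg
  bad$analysis$step_ms <- -5
  expect_error(validate_config(bad), "analysis.step_ms")
  bad2 <- cfg
  bad2$simulate$preset <- "nonsense"
  expect_error(validate_config(bad2), "simulate.preset")
  bad3 <- cfg
  bad3$analysis$n_pseudo_trials <- 2L
  expect_error(validate_config(bad3), "n_pseudo_trials")
})

test_that("config files round-trip through YAML with defaults filled in", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(seed = 7,
                        analysis = list(deltas = c(30, 60))), path)
  cfg <- read_config(path)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$analysis$deltas, c(30, 60))
  expect_equal(cfg$analysis$window_ms, 100)  # default preserved
  expect_error(read_config(file.path(dir, "none.yaml")), "not found")
})

test_that("the default configuration encodes the canonical analysis", {
  cfg <- default_config()
  expect_equal(cfg$analysis$window_ms, 100)
  expect_equal(cfg$analysis$step_ms, 20)
  expect_equal(cfg$analysis$range_ms, c(-450, 950))
  expect_equal(cfg$analysis$folds * cfg$analysis$repeats, 25L)
  expect_equal(cfg$analysis$bin_alpha, 0.001)
  expect_equal(cfg$analysis$min_run, 5L)
  expect_equal(cfg$subsample$sizes$TE, c(12L, 24L, 48L, 96L))
  expect_equal(cfg$subsample$sizes$TEO, c(12L, 24L, 48L, 72L))
})

test_that("run_simulate writes a reproducible dataset with provenance", {
  cfg <- small_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_simulate(cfg, d1)
  run_simulate(cfg, d2)
  for (f in c("spikes.csv", "catalog.csv", "cells.json", "provenance.json")) {
    expect_true(file.exists(file.path(d1, f)))
  }
  expect_identical(unname(tools::md5sum(file.path(d1, "spikes.csv"))),
                   unname(tools::md5sum(file.path(d2, "spikes.csv"))))
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"))
  expect_equal(prov$config$seed, 5)
  # the default preset spans the four recorded cell groups
  pc_cells <- build_population(sim_config(groups = preset_paper_counts(),
                                          seed = 1))$cells
  expect_equal(nrow(unique(pc_cells[, c("area", "experience")])), 4L)
})

test_that("run_decode writes per-condition results and a run summary", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  run_simulate(cfg, dir)
  res <- run_decode(cfg, dir)
  expect_true(file.exists(file.path(dir, "dprime_TE_object_task_d30.csv")))
  expect_true(file.exists(file.path(dir,
                                    "significance_TEO_object_task_d30.csv")))
  summary <- jsonlite::read_json(file.path(dir, "run_summary.json"))
  expect_equal(summary$n_bins_per_timecourse, 26L)
  expect_equal(summary$n_tested_bins,
               summary$n_conditions * summary$n_deltas *
                 summary$n_bins_per_timecourse)
  dp <- read.csv(file.path(dir, "dprime_TE_object_task_d30.csv"),
                 check.names = FALSE)
  expect_setequal(names(dp),
                  c("bin_center_ms", "repeat", "fold", "dprime", "is_null"))
  expect_equal(nrow(dp), 26 * 25 * 2)
  # rerunning on the identical inputs gives identical numbers
  dir2 <- withr::local_tempdir()
  run_simulate(cfg, dir2)
  run_decode(cfg, dir2)
  expect_identical(unname(tools::md5sum(file.path(
    dir, "dprime_TE_object_task_d30.csv"))),
    unname(tools::md5sum(file.path(dir2, "dprime_TE_object_task_d30.csv"))))
})

test_that("run_report renders figures and the interval summary", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  run_simulate(cfg, dir)
  run_decode(cfg, dir)
  run_report(dir)
  figs <- list.files(file.path(dir, "figures"))
  expect_true("timecourse_TE_object_task_d30.pdf" %in% figs)
  expect_true("timecourse_TE_object_task_d30.csv" %in% figs)
  expect_true(file.exists(file.path(dir, "summary_intervals.csv")))
  plotted <- read.csv(file.path(dir, "figures",
                                "timecourse_TE_object_task_d30.csv"))
  expect_setequal(unique(plotted$is_null), c(FALSE, TRUE))
  expect_equal(nrow(plotted), 26 * 2)
  expect_error(run_report(withr::local_tempdir()), "no decode results")
})
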