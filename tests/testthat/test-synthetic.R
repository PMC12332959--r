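# Synthetic spike generator: cell populations and Poisson spiking.

test_that("population presets match the recorded-population cell counts", {
  pc <- preset_paper_counts()
  expect_equal(sum(pc$n_cells[pc$area == "TE"]), 109L)
  expect_equal(sum(pc$n_cells[pc$area == "TEO"]), 105L)
  pop <- build_population(sim_config(groups = pc, seed = 3))
  expect_equal(sum(pop$cells$area == "TE" &
                     pop$cells$experience == "object_task"), 60L)
  expect_equal(nrow(pop$cells), 214L)
})

test_that("populations are reproducible and group sizes honor the config", {
  cfg <- sim_config(groups = tiny_groups(), seed = 11)
  p1 <- build_population(cfg)
  p2 <- build_population(cfg)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$tuning, p2$tuning)
  expect_error(sim_config(groups = tiny_groups(n_te = 0L)), "n_cells")
})

test_that("association strength sampling hits its configured mean", {
  n <- 400L
  conc <- 20
  m <- 0.1
  cfg <- sim_config(groups = tibble::tibble(
    area = "TEO", experience = "object_task", n_cells = n,
    alpha_mean = m, animal = "simA"), seed = 5, alpha_concentration = conc)
  pop <- build_population(cfg)
  a <- pop$cells$association_strength
  se <- sqrt(m * (1 - m) / (conc + 1)) / sqrt(n)  # beta variance / n
  expect_lt(abs(mean(a) - m), 3 * se)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("alpha = 1 cells have identical tuning across views of an object", {
  cfg <- sim_config(groups = tibble::tibble(
    area = "TE", experience = "object_task", n_cells = 5L,
    alpha_mean = 1, animal = "simA"), seed = 2)
  pop <- build_population(cfg)
  for (o in 1:4) {
    cols <- pop$catalog$object_id == o
    gains <- pop$tuning[, cols, drop = FALSE]
    expect_equal(unname(apply(gains, 1, max) - apply(gains, 1, min)),
                 rep(0, 5), tolerance = 1e-12)
  }
})

test_that("cross-view gain correlation increases with alpha", {
  cors <- vapply(c(0, 0.5, 1), function(a) {
    cfg <- sim_config(groups = tibble::tibble(
      area = "TE", experience = "object_task", n_cells = 120L,
      alpha_mean = a, animal = "simA"), seed = 9)
    pop <- build_population(cfg)
    v0 <- pop$tuning[, pop$catalog$view_angle_deg == 0]
    v90 <- pop$tuning[, pop$catalog$view_angle_deg == 90]
    cor(as.vector(v0), as.vector(v90))
  }, numeric(1))
  expect_lt(abs(cors[1]), 0.15)       # independent views
  expect_gt(cors[2], cors[1] + 0.1)   # monotone in alpha
  expect_gt(cors[3], 0.999)           # identical views
})

test_that("spike counts match Poisson rate x duration for constant rate", {
  # all tuning gains zero: rate is the baseline everywhere
  cfg <- sim_config(groups = tibble::tibble(
    area = "TE", experience = "object_task", n_cells = 1L,
    alpha_mean = 0.5, animal = "simA"),
    n_trials_per_image = 13L, seed = 21,
    gain_meanlog = -Inf)   # log-normal gains degenerate at 0
  pop <- build_population(cfg)
  expect_true(all(pop$tuning[!is.na(pop$tuning)] == 0))
  spk <- simulate_spikes(pop)
  rate <- pop$cells$baseline_rate[1]
  dur_s <- 0.95
  in_win <- spk$spikes$spike_time_ms >= 0 & spk$spikes$spike_time_ms < 950
  counts <- tabulate(
    (match(image_key_test(spk$spikes), spk$catalog$image_id)[in_win] - 1L) *
      13L + spk$spikes$trial_id[in_win],
    nbins = 16L * 13L)
  lambda <- rate * dur_s
  n <- length(counts)  # 208 trials
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / n))
  # variance consistent with Poisson (moment SE of the sample variance)
  se_var <- sqrt((lambda + 2 * lambda^2) / n)
  expect_lt(abs(var(counts) - lambda), 4 * se_var)
})

test_that("zero baseline and zero gain produce no spikes", {
  cfg <- sim_config(groups = tibble::tibble(
    area = "TE", experience = "object_task", n_cells = 2L,
    alpha_mean = 0.5, animal = "simA"), seed = 4,
    baseline_meanlog = -Inf, gain_meanlog = -Inf)
  spk <- simulate_spikes(build_population(cfg))
  expect_equal(nrow(spk$spikes), 0L)
})

test_that("alpha = 1 cells have identical expected evoked rate at 0 and 90 deg", {
  cfg <- sim_config(groups = tibble::tibble(
    area = "TE", experience = "object_task", n_cells = 3L,
    alpha_mean = 1, animal = "simA"), seed = 6)
  pop <- build_population(cfg)
  # expected rate after latency is baseline + phase_gain * tuning; with
  # alpha = 1 the tuning is equal across views, hence so is the rate
  for (o in 1:4) {
    g0 <- pop$tuning[, pop$catalog$object_id == o &
                       pop$catalog$view_angle_deg == 0]
    g90 <- pop$tuning[, pop$catalog$object_id == o &
                        pop$catalog$view_angle_deg == 90]
    expect_equal(unname(g0), unname(g90), tolerance = 1e-12)
  }
})

test_that("identical configuration gives byte-identical spike tables", {
  s1 <- tiny_spikes(seed = 31)
  s2 <- tiny_spikes(seed = 31)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- tiny_spikes(seed = 32)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("spike tables round-trip through the CSV + JSON layout", {
  dir <- withr::local_tempdir()
  s1 <- tiny_spikes(seed = 8, n_trials = 6L, n_te = 3L, n_teo = 2L)
  write_spike_events(s1, dir)
  expect_true(all(file.exists(file.path(dir, c("spikes.csv", "catalog.csv",
                                               "cells.json")))))
  s2 <- read_spike_events(dir)
  expect_equal(s2$n_trials_per_image, s1$n_trials_per_image)
  expect_equal(as.data.frame(s2$spikes), as.data.frame(s1$spikes),
               tolerance = 1e-9)
  expect_equal(s2$cells$cell_id, s1$cells$cell_id)
})
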