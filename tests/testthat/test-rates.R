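# Sliding-window rates, baseline subtraction, normalization.

test_that("the default grid has 71 bins and obeys the closed form", {
  g <- bin_grid()
  expect_equal(length(g), 71L)
  expect_equal(g[1], -450)
  expect_equal(g[71], 950)
  for (i in 1:20) {
    set.seed(i)
    start <- sample(-500:0, 1)
    step <- sample(c(5, 10, 20, 25, 50), 1)
    end <- start + sample(1:1000, 1)
    expect_equal(length(bin_grid(c(start, end), step)),
                 floor((end - start) / step) + 1)
  }
})

test_that("a 100 ms window counts spikes as count / window", {
  # 3 spikes at 10, 50, 89 ms; bin centered 50 covers [0, 100) -> 30 sp/s
  df <- spike_rows("c01", 1, 0, list(c(10, 50, 89)))
  spk <- manual_spikes(df, n_trials = 1, n_cells = 1)
  rt <- bin_rates(spk)
  b50 <- which(rt$bin_centers == 50)
  tr <- which(rt$trials$object_id == 1 & rt$trials$view_angle_deg == 0)
  expect_equal(rt$values[1, tr, b50], 30)
  # bin centered 150 covers [100, 200): none of the spikes
  expect_equal(rt$values[1, tr, which(rt$bin_centers == 150)], 0)
  # window edges: [40, 140) holds the spikes at 50 and 89; [80, 180) only 89
  expect_equal(rt$values[1, tr, which(rt$bin_centers == 90)], 20)
  expect_equal(rt$values[1, tr, which(rt$bin_centers == 130)], 10)
})

test_that("trials without spikes give all-zero rows and spikes outside the trial window fail", {
  df <- spike_rows("c01", 1, 0, list(c(0)))
  spk <- manual_spikes(df, n_trials = 2, n_cells = 1)
  rt <- bin_rates(spk)
  empty_tr <- which(rt$trials$object_id == 1 & rt$trials$view_angle_deg == 0 &
                      rt$trials$trial_id == 2)
  expect_true(all(rt$values[1, empty_tr, ] == 0))
  bad <- manual_spikes(spike_rows("c01", 1, 0, list(c(1200))), 1, n_cells = 1)
  expect_error(bin_rates(bad), "outside the trial window")
  expect_error(bin_rates(spk, range_ms = c(-450, 980)),
               "outside the trial window")
})

test_that("baseline subtraction removes a constant rate and keeps suppression", {
  # constant 10 sp/s: one spike every 100 ms over the whole trial
  times <- seq(-499.95, 999, by = 100)
  df <- spike_rows("c01", 1, 0, list(times))
  spk <- manual_spikes(df, n_trials = 1, n_cells = 1)
  rt <- subtract_baseline(bin_rates(spk))
  tr <- which(rt$trials$object_id == 1 & rt$trials$view_angle_deg == 0)
  expect_equal(max(abs(rt$values[1, tr, ])), 0)
  # evoked 30 sp/s on top of a 6 sp/s baseline -> 24 after subtraction
  base <- seq(-450, -50, by = 200)                 # 3 spikes: 6 sp/s baseline
  evoked <- seq(210, 290, by = 40)                 # 3 spikes in [200, 300)
  df2 <- spike_rows("c02", 1, 0, list(c(base, evoked)))
  spk2 <- manual_spikes(df2, n_trials = 1, n_cells = 1)
  spk2$cells$cell_id <- "c02"
  rt2 <- subtract_baseline(bin_rates(spk2))
  expect_equal(rt2$values[1, tr, which(rt2$bin_centers == 250)], 30 - 6)
  # bins before onset may go negative after subtraction
  expect_lt(min(rt2$values[1, tr, ]), 0)
})

test_that("normalization matches the (r - mean) / sd definition", {
  # a cell whose pooled (trial, bin) entries are {1, 2, 3}: mean 2 and
  # sample SD 1, hence normalized values {-1, 0, 1}
  rt <- structure(list(
    values = array(c(1, 2, 3), dim = c(1, 3, 1)),
    cells = tibble::tibble(cell_id = "c01", area = "TE",
                           experience = "object_task"),
    trials = tibble::tibble(trial_index = 1:3, image_index = 1L,
                            trial_id = 1:3, image_id = "img1"),
    bin_centers = 50, window_ms = 100, step_ms = 20,
    stage = "baseline_subtracted",
    baseline_rate = matrix(0, 1, 3), baseline_window_ms = c(-500, 0)),
    class = "rate_tensor")
  out <- normalize_cells(rt)
  expect_equal(as.vector(out$rates$values), c(-1, 0, 1))
  expect_equal(out$stats$r_mean, 2)
  expect_equal(out$stats$r_std, 1)
})

test_that("normalized tensors have pooled mean 0 / sd 1 and are idempotent", {
  spk <- tiny_spikes(seed = 14, n_trials = 6L)
  rt <- subtract_baseline(bin_rates(spk))
  out <- normalize_cells(rt)
  for (i in seq_len(nrow(out$rates$cells))) {
    v <- out$rates$values[i, , ]
    v <- v[!is.na(v)]
    expect_lt(abs(mean(v)), 1e-9)
    expect_lt(abs(sd(v) - 1), 1e-9)
  }
  again <- normalize_cells(out$rates)
  expect_lt(max(abs(again$rates$values - out$rates$values), na.rm = TRUE),
            1e-9)
})

test_that("zero-variance cells are reported and excluded", {
  df <- spike_rows("c01", 1, 0, list(numeric(0), numeric(0)))
  # cell c01 never spikes; a second cell carries signal
  df2 <- rbind(spike_rows("c02", 1, 0, list(c(10, 20, 30), c(50))),
               spike_rows("c02", 2, 30, list(c(100), numeric(0))))
  spk <- manual_spikes(df2, n_trials = 2, n_cells = 2)
  rt <- bin_rates(spk)
  expect_warning(out <- normalize_cells(rt), "zero-variance")
  expect_equal(out$stats$excluded, c(TRUE, FALSE))
  expect_equal(nrow(out$rates$cells), 1L)
  # a lone constant-rate cell cannot be normalized at all
  solo <- manual_spikes(spike_rows("c01", 1, 0, list(numeric(0))),
                        1, n_cells = 1)
  rt_solo <- bin_rates(solo)
  expect_warning(expect_error(normalize_cells(rt_solo), "no cell"),
                 "zero-variance")
})
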