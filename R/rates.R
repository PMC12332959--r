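#' Time-bin grid
#'
#' Bin centers for the sliding-window analysis: `range_ms[1]` to
#' `range_ms[2]` in steps of `step_ms`.  The number of bins follows the
#' closed form `floor((end - start) / step) + 1`; the default grid
#' (-450 to 950 ms, 20 ms steps) has 71 bins.
#'
#' @param range_ms Numeric length-2: first and last bin center (ms).
#' @param step_ms Step between bin centers (ms).
#' @return Numeric vector of bin centers.
#' @export
bin_grid <- function(range_ms = c(-450, 950), step_ms = 20) {
  if (step_ms <= 0) stop_user("step_ms must be positive")
  if (range_ms[2] < range_ms[1]) stop_user("range_ms must be increasing")
  seq(range_ms[1], range_ms[1] +
        floor((range_ms[2] - range_ms[1]) / step_ms) * step_ms, by = step_ms)
}

#' Sliding-window spike rates
#'
#' Converts a spike-event table to a rate tensor indexed by
#' (cell, trial, time bin).  The bin labeled `t` covers the window
#' `[t - window/2, t + window/2)` and its rate is the spike count divided by
#' the window length.  The trial dimension enumerates (image, trial) pairs;
#' entries for images never presented to a cell are `NA`.  Per-trial
#' spontaneous rates over `baseline_window_ms` are computed alongside for
#' later baseline subtraction.
#'
#' @param x A `spike_events` object.
#' @param window_ms Window length (ms), default 100.
#' @param step_ms Window step (ms), default 20.
#' @param range_ms First and last bin center, default `c(-450, 950)`.
#' @param baseline_window_ms Pre-stimulus window for the spontaneous rate,
#'   default `[-500, 0)`.
#' @return An object of class `rate_tensor`: list with `values`
#'   (3-d array cell x trial x bin, spikes/s), `cells`, `trials` (tibble
#'   describing the trial dimension), `bin_centers`, `window_ms`, `step_ms`,
#'   `stage`, `baseline_rate` (cell x trial matrix) and `baseline_window_ms`.
#' @export
bin_rates <- function(x, window_ms = 100, step_ms = 20,
                      range_ms = c(-450, 950),
                      baseline_window_ms = c(-500, 0)) {
  stopifnot(inherits(x, "spike_events"))
  if (window_ms <= 0 || step_ms <= 0) {
    stop_user("window_ms and step_ms must be positive")
  }
  if (nrow(x$cells) == 0L) stop_user("empty cell roster")
  tw <- x$trial_window_ms
  centers <- bin_grid(range_ms, step_ms)
  if (centers[1] - window_ms / 2 < tw[1] ||
      centers[length(centers)] + window_ms / 2 > tw[2]) {
    stop_user("analysis bins extend outside the trial window [",
              tw[1], ", ", tw[2], "] ms")
  }
  if (baseline_window_ms[1] < tw[1]) {
    stop_user("baseline window not covered by the trial window")
  }
  sp <- x$spikes
  if (nrow(sp) > 0 &&
      (min(sp$spike_time_ms) < tw[1] || max(sp$spike_time_ms) >= tw[2])) {
    stop_user("spike times outside the trial window")
  }

  catalog <- x$catalog
  n_tr <- x$n_trials_per_image
  n_cells <- nrow(x$cells)
  n_img <- nrow(catalog)
  n_trials <- n_img * n_tr
  n_bins <- length(centers)

  trials <- tibble(
    trial_index = seq_len(n_trials),
    image_index = rep(seq_len(n_img), each = n_tr),
    trial_id = rep(seq_len(n_tr), n_img)
  )
  trials$set_id <- catalog$set_id[trials$image_index]
  trials$object_id <- catalog$object_id[trials$image_index]
  trials$view_angle_deg <- catalog$view_angle_deg[trials$image_index]
  trials$image_id <- catalog$image_id[trials$image_index]
  trials$experience <- catalog$experience[trials$image_index]

  # map spikes to (cell, trial-row)
  cidx <- match(sp$cell_id, x$cells$cell_id)
  iidx <- match(image_key(sp$set_id, sp$object_id, sp$view_angle_deg),
                catalog$image_id)
  if (anyNA(cidx) || anyNA(iidx)) {
    stop_user("spike table refers to unknown cells or images")
  }
  if (any(sp$trial_id < 1 | sp$trial_id > n_tr)) {
    stop_user("trial_id outside 1..n_trials_per_image")
  }
  trow <- (iidx - 1L) * n_tr + sp$trial_id
  ct <- cidx + (trow - 1L) * n_cells

  # each spike falls in bins with center in (t - w/2, t + w/2]
  k0 <- floor((sp$spike_time_ms - window_ms / 2 - centers[1]) / step_ms) + 1
  k1 <- floor((sp$spike_time_ms + window_ms / 2 - centers[1]) / step_ms)
  n_ct <- n_cells * n_trials
  counts <- numeric(n_ct * n_bins)
  max_span <- ceiling(window_ms / step_ms) + 1
  for (off in 0:(max_span - 1)) {
    k <- k0 + off
    ok <- k <= k1 & k >= 0 & k < n_bins
    if (any(ok)) {
      idx <- ct[ok] + k[ok] * n_ct
      tab <- tabulate(idx, nbins = n_ct * n_bins)
      counts <- counts + tab
    }
  }
  values <- array(counts / (window_ms / 1000), dim = c(n_cells, n_trials, n_bins),
                  dimnames = list(x$cells$cell_id, NULL, centers))

  # mask (cell, image) pairs never presented
  if (!is.null(x$cells$experience)) {
    presented <- outer(x$cells$experience, trials$experience, "==")
    if (!all(presented)) {
      values[rep(!presented, times = n_bins)] <- NA_real_
    }
  }

  # per-trial spontaneous rate
  inb <- sp$spike_time_ms >= baseline_window_ms[1] &
    sp$spike_time_ms < baseline_window_ms[2]
  bl_counts <- tabulate(ct[inb], nbins = n_ct)
  baseline_rate <- matrix(
    bl_counts / ((baseline_window_ms[2] - baseline_window_ms[1]) / 1000),
    n_cells, n_trials)

  structure(list(values = values, cells = x$cells, trials = trials,
                 bin_centers = centers, window_ms = window_ms,
                 step_ms = step_ms, stage = "raw",
                 baseline_rate = baseline_rate,
                 baseline_window_ms = baseline_window_ms),
            class = "rate_tensor")
}

#' Subtract per-trial spontaneous rates
#'
#' Subtracts each trial's mean spontaneous rate (computed over the
#' pre-stimulus baseline window when the tensor was binned) from every time
#' bin of that trial.  Values may become negative (response suppression).
#'
#' @param rates A raw `rate_tensor`.
#' @param baseline_window_ms Baseline window; must equal the window used by
#'   [bin_rates()].
#' @return The tensor with stage `"baseline_subtracted"`.
#' @export
subtract_baseline <- function(rates, baseline_window_ms = c(-500, 0)) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (rates$stage != "raw") {
    stop_user("baseline subtraction expects a raw rate tensor")
  }
  if (!isTRUE(all.equal(baseline_window_ms, rates$baseline_window_ms))) {
    stop_user("baseline window ", baseline_window_ms[1], "..",
              baseline_window_ms[2],
              " ms was not precomputed; re-run bin_rates() with it")
  }
  # [cell, trial] recycles over the bin dimension in the linear layout
  rates$values <- rates$values - as.vector(rates$baseline_rate)
  rates$stage <- "baseline_subtracted"
  rates
}

#' Per-cell z-normalization
#'
#' Normalizes each cell's rates as `(r - r_mean) / r_std`, with `r_mean` and
#' `r_std` the mean and sample standard deviation pooled over all of the
#' cell's (trial, bin) entries in the analysis range.  Cells with zero
#' variance cannot be normalized; they are reported and excluded with a
#' warning (an error if no cell survives).
#'
#' @param rates A `rate_tensor` (typically baseline-subtracted).
#' @return A list with `rates` (the normalized tensor, zero-variance cells
#'   dropped) and `stats` (tibble: `cell_id`, `r_mean`, `r_std`, `excluded`).
#' @export
normalize_cells <- function(rates) {
  stopifnot(inherits(rates, "rate_tensor"))
  n_cells <- dim(rates$values)[1]
  m <- numeric(n_cells)
  s <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    v <- rates$values[i, , ]
    v <- v[!is.na(v)]
    m[i] <- mean(v)
    s[i] <- sd(v)
  }
  excluded <- s < 1e-12 | !is.finite(s)
  stats <- tibble(cell_id = rates$cells$cell_id, r_mean = m, r_std = s,
                  excluded = excluded)
  if (any(excluded)) {
    warning("excluding ", sum(excluded),
            " zero-variance cell(s): ",
            paste(stats$cell_id[excluded], collapse = ", "))
    if (all(excluded)) stop_user("no cell with positive rate variance")
  }
  keep <- which(!excluded)
  # cell is the fastest-varying dimension, so the per-cell m and s vectors
  # recycle correctly along the trial and bin dimensions
  rates$values <- (rates$values - m) / s
  rates$values <- rates$values[keep, , , drop = FALSE]
  rates$cells <- rates$cells[keep, ]
  rates$baseline_rate <- rates$baseline_rate[keep, , drop = FALSE]
  rates$stage <- "normalized"
  list(rates = rates, stats = stats)
}
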