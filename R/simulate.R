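#' Simulate spike trains for a cell population
#'
#' Draws spikes from an inhomogeneous Poisson process for every
#' (cell, image, trial) combination in which the image's experience condition
#' matches the cell's.  The rate is the cell's baseline before its response
#' latency; `baseline + early_phase_gain * g` from latency to the phase
#' boundary; `baseline + late_phase_gain * g` up to the end of the stimulus
#' epoch; and decays exponentially back to baseline afterwards.  Spikes are
#' sampled by thinning a homogeneous process at the cell's peak rate, so the
#' rate is non-negative by construction.  Trials are independent and the
#' whole table is reproducible from the configuration seed.
#'
#' @param population A [build_population()] result.
#' @param catalog,config Stimulus catalog and configuration; default to those
#'   stored in `population`.
#' @return An object of class `spike_events`: a list with `spikes` (tibble
#'   with one row per spike: `cell_id`, `area`, `animal`, `experience`,
#'   `set_id`, `object_id`, `view_angle_deg`, `trial_id`, `spike_time_ms`),
#'   `cells`, `catalog`, `n_trials_per_image` and `trial_window_ms`.
#' @export
simulate_spikes <- function(population, catalog = population$catalog,
                            config = population$config) {
  stopifnot(inherits(population, "cell_population"))
  cells <- population$cells
  tun <- population$tuning
  tw <- config$trial_window_ms
  dur_s <- (tw[2] - tw[1]) / 1000
  n_tr <- config$n_trials_per_image

  pairs <- which(!is.na(tun), arr.ind = TRUE)  # (cell, image) presented pairs
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  ci <- pairs[, 1L]
  im <- pairs[, 2L]
  B <- cells$baseline_rate[ci]
  g <- tun[pairs]
  E <- cells$early_phase_gain[ci]
  L <- cells$late_phase_gain[ci]
  lat <- cells$latency_ms[ci]
  rmax <- B + g * pmax(E, L)

  with_seed(derive_seed(config$seed, 101L), {
    # candidate spikes from the bounding homogeneous process, then thinning
    n_pairs <- length(ci)
    counts <- rpois(n_pairs * n_tr, rep(rmax, each = n_tr) * dur_s)
    trial_of <- rep(rep(seq_len(n_tr), n_pairs), counts)
    pair_of <- rep(rep(seq_len(n_pairs), each = n_tr), counts)
    tms <- runif(length(pair_of), tw[1], tw[2])
    rate <- evoked_rate(tms, B[pair_of], g[pair_of], E[pair_of], L[pair_of],
                        lat[pair_of], config$phase_boundary_ms,
                        config$stim_end_ms, config$decay_tau_ms)
    tms <- round(tms, 3)
    keep <- runif(length(tms)) * rmax[pair_of] < rate
    keep <- keep & tms >= tw[1] & tms < tw[2]  # guard the rounding at edges
    trial_of <- trial_of[keep]
    pair_of <- pair_of[keep]
    tms <- tms[keep]
    ord <- order(pair_of, trial_of, tms)
    trial_of <- trial_of[ord]
    pair_of <- pair_of[ord]
    tms <- tms[ord]

    cidx <- ci[pair_of]
    iidx <- im[pair_of]
    spikes <- tibble(
      cell_id = cells$cell_id[cidx],
      area = cells$area[cidx],
      animal = cells$animal[cidx],
      experience = cells$experience[cidx],
      set_id = catalog$set_id[iidx],
      object_id = catalog$object_id[iidx],
      view_angle_deg = catalog$view_angle_deg[iidx],
      trial_id = trial_of,
      spike_time_ms = tms
    )
    structure(list(spikes = spikes, cells = cells, catalog = catalog,
                   n_trials_per_image = n_tr, trial_window_ms = tw,
                   config = config),
              class = "spike_events")
  })
}

# Piecewise evoked-rate profile shared by the simulator and its tests.
evoked_rate <- function(t, baseline, gain, early, late, latency,
                        boundary, stim_end, tau) {
  evoked <- numeric(length(t))
  phase_early <- t >= latency & t < boundary
  phase_late <- t >= pmax(latency, boundary) & t < stim_end
  phase_decay <- t >= stim_end
  evoked[phase_early] <- (early * gain)[phase_early]
  evoked[phase_late] <- (late * gain)[phase_late]
  evoked[phase_decay] <- ((late * gain) * exp(-(t - stim_end) / tau))[phase_decay]
  baseline + evoked
}

#' @export
print.spike_events <- function(x, ...) {
  cat("<spike_events> ", nrow(x$spikes), " spikes, ", nrow(x$cells),
      " cells, ", nrow(x$catalog), " images, ", x$n_trials_per_image,
      " trials/image, window [", x$trial_window_ms[1], ", ",
      x$trial_window_ms[2], "] ms\n", sep = "")
  invisible(x)
}

#' Write / read a spike-event table
#'
#' The spike table is written as a plain CSV with header
#' `cell_id,area,animal,experience,set_id,object_id,view_angle_deg,trial_id,spike_time_ms`
#' (times in ms relative to stimulus onset, negative times allowed), with the
#' cell metadata in a JSON sidecar and the catalog as a second CSV.
#'
#' @param x A `spike_events` object.
#' @param dir Output/input directory.
#' @return `write_spike_events()` returns `dir` invisibly;
#'   `read_spike_events()` returns a `spike_events` object.
#' @export
write_spike_events <- function(x, dir) {
  stopifnot(inherits(x, "spike_events"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(as.data.frame(x$spikes), file.path(dir, "spikes.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(x$catalog), file.path(dir, "catalog.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(cells = x$cells,
         n_trials_per_image = x$n_trials_per_image,
         trial_window_ms = x$trial_window_ms),
    file.path(dir, "cells.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(dir) {
  fs <- file.path(dir, c("spikes.csv", "catalog.csv", "cells.json"))
  missing <- fs[!file.exists(fs)]
  if (length(missing)) {
    stop_user("missing input file(s): ", paste(missing, collapse = ", "))
  }
  spikes <- as_tibble(read.csv(fs[1], stringsAsFactors = FALSE))
  catalog <- as_tibble(read.csv(fs[2], stringsAsFactors = FALSE))
  meta <- jsonlite::read_json(fs[3], simplifyVector = TRUE)
  structure(list(spikes = spikes, catalog = catalog,
                 cells = as_tibble(meta$cells),
                 n_trials_per_image = as.integer(meta$n_trials_per_image),
                 trial_window_ms = as.numeric(meta$trial_window_ms),
                 config = NULL),
            class = "spike_events")
}
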