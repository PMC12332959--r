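#' Default run configuration
#'
#' Returns the full configuration of a simulate-decode-report run with the
#' canonical analysis parameters: 100 ms windows stepped by 20 ms over
#' -450..950 ms (71 bins), per-trial baseline subtraction over [-500, 0) ms,
#' responsiveness screening over [0, 600) ms at Bonferroni-corrected 0.05,
#' 20 pseudo-trials split 5 folds x 5 repeats (25 estimates per bin),
#' viewing-angle differences 30/60/90, per-bin threshold 0.001 with the
#' 5-consecutive-bin rule, and subsampling sizes 12/24/48/96 (TE) and
#' 12/24/48/72 (TEO).
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param preset `"paper_counts"` (four recorded-population-sized groups) or
#'   `"two_population"` (compact TE-like vs TEO-like contrast).
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L, preset = c("paper_counts",
                                                 "two_population")) {
  preset <- match.arg(preset)
  list(
    seed = as.integer(seed),
    simulate = list(
      preset = preset,
      n_trials_per_image = 40L,
      trial_window_ms = c(-500, 1000)
    ),
    analysis = list(
      window_ms = 100, step_ms = 20, range_ms = c(-450, 950),
      baseline_window_ms = c(-500, 0),
      evoked_window_ms = c(0, 600), screen_alpha = 0.05,
      n_pseudo_trials = 20L, folds = 5L, repeats = 5L,
      deltas = c(30L, 60L, 90L),
      bin_alpha = 0.001, min_run = 5L,
      cost = 1, responsive_only = TRUE
    ),
    subsample = list(
      enabled = FALSE,
      sizes = list(TE = c(12L, 24L, 48L, 96L), TEO = c(12L, 24L, 48L, 72L)),
      n_draws = 5L, window_ms = c(100, 600), delta = 30L
    )
  )
}

#' Validate a run configuration
#'
#' Checks types and ranges of every configuration key, raising an error that
#' names the offending key.
#'
#' @param config A configuration list (see [default_config()]).
#' @return The validated configuration, invisibly.
#' @export
validate_config <- function(config) {
  chk <- function(ok, key, what) {
    if (!isTRUE(ok)) stop_user("invalid config key '", key, "': ", what)
  }
  chk(is.list(config), "(root)", "must be a list")
  chk(is.numeric(config$seed) && length(config$seed) == 1L,
      "seed", "must be a single integer")
  s <- config$simulate
  chk(is.list(s), "simulate", "must be a list")
  chk(is.character(s$preset) &&
        s$preset %in% c("paper_counts", "two_population"),
      "simulate.preset", "must be 'paper_counts' or 'two_population'")
  chk(is.numeric(s$n_trials_per_image) && s$n_trials_per_image >= 2,
      "simulate.n_trials_per_image", "must be an integer >= 2")
  chk(is.numeric(s$trial_window_ms) && length(s$trial_window_ms) == 2L &&
        s$trial_window_ms[1] <= -500 && s$trial_window_ms[2] >= 950,
      "simulate.trial_window_ms",
      "must cover [-500, 950] ms")
  a <- config$analysis
  chk(is.list(a), "analysis", "must be a list")
  chk(is.numeric(a$window_ms) && a$window_ms > 0, "analysis.window_ms",
      "must be positive")
  chk(is.numeric(a$step_ms) && a$step_ms > 0, "analysis.step_ms",
      "must be positive")
  chk(is.numeric(a$range_ms) && length(a$range_ms) == 2L &&
        a$range_ms[2] >= a$range_ms[1], "analysis.range_ms",
      "must be an increasing pair")
  chk(is.numeric(a$n_pseudo_trials) && a$n_pseudo_trials >= a$folds,
      "analysis.n_pseudo_trials", "must be >= folds")
  chk(is.numeric(a$folds) && a$folds >= 2, "analysis.folds", "must be >= 2")
  chk(is.numeric(a$repeats) && a$repeats >= 1, "analysis.repeats",
      "must be >= 1")
  chk(all(a$deltas %in% VIEW_ANGLES), "analysis.deltas",
      "must be a subset of 0/30/60/90")
  chk(is.numeric(a$bin_alpha) && a$bin_alpha > 0 && a$bin_alpha < 1,
      "analysis.bin_alpha", "must be in (0, 1)")
  chk(is.numeric(a$min_run) && a$min_run >= 1, "analysis.min_run",
      "must be >= 1")
  invisible(config)
}

#' Read a configuration file
#'
#' Reads a YAML or JSON run configuration, fills unspecified keys from
#' [default_config()] and validates the result.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_user("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  config <- modify_list(default_config(), user)
  validate_config(config)
  config
}

modify_list <- function(base, new) {
  for (k in names(new)) {
    if (is.list(new[[k]]) && is.list(base[[k]])) {
      base[[k]] <- modify_list(base[[k]], new[[k]])
    } else {
      base[[k]] <- new[[k]]
    }
  }
  base
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

config_groups <- function(config) {
  if (!is.null(config$simulate$groups)) {
    return(as_tibble(as.data.frame(config$simulate$groups)))
  }
  switch(config$simulate$preset,
         paper_counts = preset_paper_counts(),
         two_population = preset_two_population())
}

#' Simulate a spike-event dataset and write it to disk
#'
#' Builds the stimulus catalog and cell population for the configured
#' preset, simulates spikes, and writes `spikes.csv`, `catalog.csv`,
#' `cells.json` and a provenance record (`provenance.json` with the full
#' configuration, derived seeds and package version) to `outdir`.
#'
#' @param config A validated configuration (see [default_config()]).
#' @param outdir Output directory (created if needed).
#' @return The `spike_events` object, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  validate_config(config)
  groups <- config_groups(config)
  sc <- sim_config(groups = groups,
                   n_trials_per_image = config$simulate$n_trials_per_image,
                   trial_window_ms = config$simulate$trial_window_ms,
                   seed = derive_seed(config$seed, 1L))
  pop <- build_population(sc)
  spk <- simulate_spikes(pop)
  write_spike_events(spk, outdir)
  jsonlite::write_json(
    list(stage = "simulate", config = config,
         config_md5 = config_hash(config),
         sim_seed = sc$seed,
         n_cells = nrow(spk$cells), n_spikes = nrow(spk$spikes),
         package = "viewdecode",
         version = as.character(utils::packageVersion("viewdecode"))),
    file.path(outdir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(spk)
}

#' Decode a spike-event dataset and write results
#'
#' Runs the full analysis for every (area, experience) condition present in
#' the data and every configured viewing-angle difference: sliding-window
#' rates, baseline subtraction, normalization, responsiveness screening,
#' pseudo-population assembly, real and random-labeling decoding, per-bin
#' Mann-Whitney tests and consecutive-bin significance.  Per condition and
#' delta it writes `dprime_<area>_<experience>_d<delta>.csv`
#' (`bin_center_ms,repeat,fold,dprime,is_null`) and
#' `significance_<...>.csv`; a run summary with cell counts, tested-bin
#' totals and significant intervals goes to `run_summary.json`.
#'
#' @param config A validated configuration.
#' @param outdir Output directory for result files.
#' @param spikes Optional `spike_events` object; by default read back from
#'   `outdir` (as written by [run_simulate()]).
#' @return A list of per-condition results, invisibly.
#' @export
run_decode <- function(config, outdir, spikes = NULL) {
  validate_config(config)
  if (is.null(spikes)) spikes <- read_spike_events(outdir)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  a <- config$analysis

  rt <- bin_rates(spikes, a$window_ms, a$step_ms, a$range_ms,
                  a$baseline_window_ms)
  rt <- subtract_baseline(rt, a$baseline_window_ms)
  norm <- normalize_cells(rt)
  report <- screen_responsive(spikes, a$evoked_window_ms, a$screen_alpha,
                              a$baseline_window_ms)
  plan <- plan_splits(a$n_pseudo_trials, a$folds, a$repeats,
                      seed = derive_seed(config$seed, 2L))

  write_responsiveness_report(report, file.path(outdir, "responsiveness"))

  groups <- unique(spikes$cells[, c("area", "experience")])
  results <- list()
  summary_conditions <- list()
  for (gi in seq_len(nrow(groups))) {
    t_start <- Sys.time()
    area <- groups$area[gi]
    exper <- groups$experience[gi]
    tag <- paste0(area, "_", exper)
    pds_list <- assemble_repeats(norm$rates, area = area,
                    experience = exper,
                    report = if (isTRUE(a$responsive_only)) report,
                    n_pseudo_trials = a$n_pseudo_trials,
                    repeats = a$repeats,
                    seed = derive_seed(config$seed, 3L + gi))
    pds <- pds_list[[1L]]
    real <- decode_timecourses(pds_list, a$deltas, plan, cost = a$cost)
    null <- decode_timecourses(pds_list, a$deltas, plan, null = TRUE,
                               null_seed = derive_seed(config$seed, 30L + gi),
                               cost = a$cost)
    cond_res <- list()
    for (di in seq_along(a$deltas)) {
      d <- a$deltas[di]
      trk <- significance_track(real[[di]], null[[di]],
                                bin_centers = pds$bin_centers,
                                alpha = a$bin_alpha, min_run = a$min_run)
      write_dprime_csv(real[[di]], null[[di]], plan, pds$bin_centers,
                       file.path(outdir, sprintf("dprime_%s_d%d.csv", tag, d)))
      write.csv(data.frame(bin_center_ms = pds$bin_centers,
                           p_value = trk$pvalues),
                file.path(outdir, sprintf("significance_%s_d%d.csv", tag, d)),
                row.names = FALSE)
      cond_res[[paste0("delta", d)]] <-
        list(real = real[[di]], null = null[[di]], track = trk)
    }
    results[[tag]] <- cond_res
    summary_conditions[[tag]] <- list(
      area = area, experience = exper,
      n_cells = length(pds$roster),
      intervals = lapply(cond_res, function(cr) cr$track$intervals),
      elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 2)
    )
  }

  if (isTRUE(config$subsample$enabled)) {
    results$subsample <- run_subsample(config, outdir, spikes, report)
  }

  n_bins <- length(bin_grid(a$range_ms, a$step_ms))
  summary <- list(
    stage = "decode",
    n_cells_recorded = nrow(spikes$cells),
    n_cells_responsive = sum(report$cells$responsive),
    conditions = summary_conditions,
    n_conditions = nrow(groups),
    n_deltas = length(a$deltas),
    n_bins_per_timecourse = n_bins,
    n_tested_bins = nrow(groups) * length(a$deltas) * n_bins
  )
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

write_dprime_csv <- function(real, null, plan, bin_centers, path) {
  folds <- plan$folds
  cols <- ncol(real)
  long <- function(m, is_null) {
    data.frame(
      bin_center_ms = rep(bin_centers, cols),
      rep = rep(((seq_len(cols) - 1L) %/% folds) + 1L, each = nrow(m)),
      fold = rep(((seq_len(cols) - 1L) %% folds) + 1L, each = nrow(m)),
      dprime = as.vector(m),
      is_null = is_null
    )
  }
  out <- rbind(long(real, FALSE), long(null, TRUE))
  names(out)[2] <- "repeat"
  write.csv(out, path, row.names = FALSE)
}

#' Subsampling analysis over a single wide window
#'
#' Re-bins the spikes with one wide window (default 100-600 ms), assembles
#' per-area datasets and computes [subsample_curve()]s at the configured
#' roster sizes, writing `subsample_<area>.csv` per area.
#'
#' @param config,outdir,spikes As in [run_decode()].
#' @param report Optional responsiveness report (recomputed if `NULL`).
#' @return Named list of `subsample_curve`s, invisibly.
#' @export
run_subsample <- function(config, outdir, spikes = NULL, report = NULL) {
  validate_config(config)
  if (is.null(spikes)) spikes <- read_spike_events(outdir)
  a <- config$analysis
  ss <- config$subsample
  win <- ss$window_ms
  center <- mean(win)
  rt <- bin_rates(spikes, window_ms = diff(win), step_ms = a$step_ms,
                  range_ms = c(center, center),
                  baseline_window_ms = a$baseline_window_ms)
  rt <- subtract_baseline(rt, a$baseline_window_ms)
  norm <- normalize_cells(rt)
  if (is.null(report)) {
    report <- screen_responsive(spikes, a$evoked_window_ms, a$screen_alpha,
                                a$baseline_window_ms)
  }
  plan <- plan_splits(a$n_pseudo_trials, a$folds, a$repeats,
                      seed = derive_seed(config$seed, 2L))
  out <- list()
  for (area in names(ss$sizes)) {
    if (!area %in% norm$rates$cells$area) next
    exper <- unique(norm$rates$cells$experience[
      norm$rates$cells$area == area])
    for (ex in exper) {
      pds <- assemble(norm$rates, area = area, experience = ex,
                      report = if (isTRUE(a$responsive_only)) report,
                      n_pseudo_trials = a$n_pseudo_trials,
                      seed = derive_seed(config$seed, 50L))
      sizes <- ss$sizes[[area]]
      sizes <- sizes[sizes <= length(pds$roster)]
      if (length(sizes) == 0L) next
      curve <- subsample_curve(pds, sizes, ss$delta, plan,
                               n_draws = ss$n_draws,
                               seed = derive_seed(config$seed, 60L),
                               cost = a$cost)
      tag <- paste0(area, "_", ex)
      write.csv(as.data.frame(curve),
                file.path(outdir, sprintf("subsample_%s_d%d.csv", tag,
                                          ss$delta)),
                row.names = FALSE)
      out[[tag]] <- curve
    }
  }
  invisible(out)
}
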