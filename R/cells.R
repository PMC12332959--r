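#' Cell-group presets
#'
#' `preset_paper_counts()` reproduces the recorded-population layout used for
#' the headline analysis: 60 and 49 TE cells responsive to object-task and
#' across-set-task images, and 40 and 65 TEO cells, i.e. 109 TE and 105 TEO
#' analysis cells in total.  `preset_two_population()` is the compact
#' two-population contrast used for qualitative reproduction: a strongly
#' view-associated TE-like group and a weakly associated TEO-like group,
#' both for object-task sets.
#'
#' `alpha_mean` is the group mean of the association strength \eqn{\alpha}:
#' the convex weight mixing a view-invariant per-object gain (weight
#' \eqn{\alpha}) with independent per-view gains (weight \eqn{1-\alpha}).
#' An optional `alpha_concentration` column overrides the global Beta
#' concentration per group (large values approach a point mass, pinning
#' every cell of the group near `alpha_mean`).
#'
#' @return A tibble with columns `area`, `experience`, `n_cells`,
#'   `alpha_mean` and `animal` (plus `alpha_concentration` for the
#'   two-population preset).
#' @export
preset_paper_counts <- function() {
  tibble(
    area = c("TE", "TE", "TEO", "TEO"),
    experience = c("object_task", "across_set_task",
                   "object_task", "across_set_task"),
    n_cells = c(60L, 49L, 40L, 65L),
    alpha_mean = c(0.8, 0.25, 0.1, 0.1),
    animal = "simA"
  )
}

#' @rdname preset_paper_counts
#' @export
preset_two_population <- function() {
  tibble(
    area = c("TE", "TEO"),
    experience = c("object_task", "object_task"),
    n_cells = c(60L, 48L),
    alpha_mean = c(0.8, 0.1),
    alpha_concentration = c(20, 1000),
    animal = "simA"
  )
}

#' Simulation configuration
#'
#' Bundles all parameters of the synthetic spike-train generator.  Rate
#' parameters are in spikes/s and times in ms relative to stimulus onset.
#' A cell's expected rate is `baseline` before its response latency;
#' from latency to `phase_boundary_ms` it is `baseline + early_gain * g`,
#' from the boundary to `stim_end_ms` it is `baseline + late_gain * g`,
#' and after `stim_end_ms` the evoked component decays exponentially with
#' time constant `decay_tau_ms`.  `g >= 0` is the cell's tuning gain for the
#' presented image.
#'
#' @param groups Tibble of cell groups (see [preset_paper_counts()]).
#' @param n_trials_per_image Trials simulated per (cell, image); >= 2.
#'   The default 40 leaves headroom over the 20 pseudo-trials drawn per
#'   repeat, so reassigned pseudo-populations resample different trials.
#' @param trial_window_ms Trial time span; must cover the 500 ms pre-stimulus
#'   baseline and the full support of the analysis bins (default
#'   `c(-500, 1000)`).
#' @param seed Integer seed making the whole simulation reproducible.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-cell spontaneous rate.
#' @param gain_meanlog,gain_sdlog Log-normal parameters of the tuning gains.
#' @param early_gain,late_gain Multipliers applied to the tuning gain in the
#'   early and late response phases.
#' @param latency_mean_ms Named vector of mean response latencies per area.
#' @param latency_sd_ms,latency_min_ms Latency jitter SD and lower bound.
#' @param phase_boundary_ms Boundary between early and late response phases.
#' @param stim_end_ms End of the sustained evoked epoch.
#' @param decay_tau_ms Exponential decay constant of the evoked rate after
#'   `stim_end_ms`.
#' @param alpha_concentration Beta-distribution concentration of the per-cell
#'   association strength around its group mean.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(groups = preset_paper_counts(),
                       n_trials_per_image = 40L,
                       trial_window_ms = c(-500, 1000),
                       seed = 1L,
                       baseline_meanlog = log(5),
                       baseline_sdlog = 0.5,
                       gain_meanlog = log(8),
                       gain_sdlog = 0.8,
                       early_gain = 1.3,
                       late_gain = 0.7,
                       latency_mean_ms = c(TE = 90, TEO = 70),
                       latency_sd_ms = 10,
                       latency_min_ms = 40,
                       phase_boundary_ms = 300,
                       stim_end_ms = 600,
                       decay_tau_ms = 100,
                       alpha_concentration = 20) {
  groups <- as_tibble(groups)
  need <- c("area", "experience", "n_cells", "alpha_mean")
  if (!all(need %in% names(groups))) {
    stop_user("groups must have columns ", paste(need, collapse = ", "))
  }
  if (is.null(groups$animal)) groups$animal <- "simA"
  if (any(groups$n_cells <= 0)) stop_user("n_cells must be positive")
  if (any(groups$alpha_mean < 0 | groups$alpha_mean > 1)) {
    stop_user("alpha_mean must lie in [0, 1]")
  }
  if (n_trials_per_image < 2) stop_user("n_trials_per_image must be >= 2")
  if (trial_window_ms[1] > -500 || trial_window_ms[2] < 950) {
    stop_user("trial_window_ms must cover the baseline window [-500, 0) ",
              "and the analysis range up to 950 ms")
  }
  if (phase_boundary_ms <= latency_min_ms) {
    stop_user("phase_boundary_ms must exceed latency_min_ms")
  }
  structure(list(
    groups = groups,
    n_trials_per_image = as.integer(n_trials_per_image),
    trial_window_ms = as.numeric(trial_window_ms),
    seed = as.integer(seed),
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    gain_meanlog = gain_meanlog, gain_sdlog = gain_sdlog,
    early_gain = early_gain, late_gain = late_gain,
    latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
    latency_min_ms = latency_min_ms,
    phase_boundary_ms = phase_boundary_ms,
    stim_end_ms = stim_end_ms, decay_tau_ms = decay_tau_ms,
    alpha_concentration = alpha_concentration
  ), class = "sim_config")
}

# Draw association strengths; degenerate means give point masses so that
# alpha = 1 yields exactly view-invariant tuning and alpha = 0 exactly
# independent per-view tuning.
draw_alpha <- function(n, mean, concentration) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  rbeta(n, mean * concentration, (1 - mean) * concentration)
}

#' Build a synthetic cell population
#'
#' Draws per-cell baseline rates, response latencies, early/late phase gains,
#' association strengths and per-image tuning gains for every cell group in
#' the configuration.  A cell is tuned only to the images whose experience
#' condition matches its group; tuning entries for other images are `NA`
#' (those images are not presented to the cell).
#'
#' Tuning structure: for each object the cell draws a shared object gain
#' `g_obj` and independent per-view gains `g_view`; the gain for an image is
#' `alpha * g_obj + (1 - alpha) * g_view`.  With `alpha = 1` the evoked rate
#' is identical across the four views of an object; with `alpha = 0` the
#' per-view gains are independent.
#'
#' @param config A [sim_config()].
#' @param catalog A stimulus catalog from [generate_catalog()]; by default one
#'   set per experience condition present in `config$groups`.
#' @return An object of class `cell_population`: a list with `cells` (tibble
#'   of per-cell parameters), `tuning` (cells x images gain matrix, spikes/s),
#'   `catalog` and `config`.
#' @export
build_population <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(catalog)) {
    exps <- unique(config$groups$experience)
    catalog <- generate_catalog(length(exps), exps)
  }
  with_seed(config$seed, {
    groups <- config$groups
    cells_list <- vector("list", nrow(groups))
    tuning_list <- vector("list", nrow(groups))
    for (gi in seq_len(nrow(groups))) {
      g <- groups[gi, ]
      n <- g$n_cells
      lat_mean <- config$latency_mean_ms[[g$area]]
      if (is.null(lat_mean)) lat_mean <- mean(config$latency_mean_ms)
      conc <- if ("alpha_concentration" %in% names(g)) g$alpha_concentration
      else config$alpha_concentration
      alpha <- draw_alpha(n, g$alpha_mean, conc)
      cells <- tibble(
        cell_id = sprintf("%s_%s_c%03d", g$area,
                          ifelse(g$experience == "object_task", "obj", "acr"),
                          seq_len(n)),
        area = g$area,
        animal = g$animal,
        experience = g$experience,
        baseline_rate = rlnorm(n, config$baseline_meanlog,
                               config$baseline_sdlog),
        association_strength = alpha,
        latency_ms = pmax(config$latency_min_ms,
                          rnorm(n, lat_mean, config$latency_sd_ms)),
        early_phase_gain = config$early_gain *
          rlnorm(n, 0, 0.1),
        late_phase_gain = config$late_gain *
          rlnorm(n, 0, 0.1),
        phase_boundary_ms = config$phase_boundary_ms
      )
      tun <- matrix(NA_real_, n, nrow(catalog),
                    dimnames = list(cells$cell_id, catalog$image_id))
      imgs <- which(catalog$experience == g$experience)
      for (s in unique(catalog$set_id[imgs])) {
        for (o in 1:4) {
          cols <- which(catalog$set_id == s & catalog$object_id == o)
          g_obj <- rlnorm(n, config$gain_meanlog, config$gain_sdlog)
          for (cc in cols) {
            g_view <- rlnorm(n, config$gain_meanlog, config$gain_sdlog)
            tun[, cc] <- alpha * g_obj + (1 - alpha) * g_view
          }
        }
      }
      cells_list[[gi]] <- cells
      tuning_list[[gi]] <- tun
    }
    cells <- do.call(rbind, cells_list)
    tuning <- do.call(rbind, tuning_list)
    structure(list(cells = cells, tuning = tuning, catalog = catalog,
                   config = config),
              class = "cell_population")
  })
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population> ", nrow(x$cells), " cells, ",
      nrow(x$catalog), " images\n", sep = "")
  tab <- table(x$cells$area, x$cells$experience)
  print(tab)
  invisible(x)
}
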